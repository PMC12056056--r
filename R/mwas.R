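#' Methylome-wide association scan
#'
#' Fits, per probe, an ordinary least squares model of the beta value on a
#' group indicator (target = 1, control = 0) plus covariates:
#' `DNAm_i ~ group + sex + age + batch + array position + cell composition`.
#' The reported effect is the group coefficient — the covariate-adjusted
#' difference in mean DNAm of the target group from the control group, on the
#' beta-value scale. Samples outside the two groups are excluded; character
#' and factor covariates are one-hot encoded dropping one level.
#'
#' All probes share a common design matrix, so the scan is performed as a
#' single multi-response least-squares solve.
#'
#' @param meth probes x samples matrix of beta values (rownames = probe ids).
#' @param sheet sample sheet `data.frame` with a `group` column and all
#'   covariate columns; rows matched to `colnames(meth)` by `sample_id`.
#' @param target_group,control_group group labels, e.g. `"AN"`, `"NL"`.
#' @param covariates character vector of sheet column names to adjust for
#'   (default none).
#' @param probes optional probe annotation data.frame (`probe_id`, `chrom`,
#'   `pos`) merged into the result.
#' @return an `assoc_table`: data.frame with columns probe, chrom, pos,
#'   effect, se, z, p_nominal, z_adj, p_adj, n; attribute `m_tests` is the
#'   number of probes with a valid test (zero-variance probes are excluded
#'   from the multiple-testing count and carry `se = NA`).
#' @export
run_mwas <- function(meth, sheet, target_group, control_group,
                     covariates = NULL, probes = NULL) {
  keep <- sheet$group %in% c(target_group, control_group)
  if (!any(sheet$group == target_group) || !any(sheet$group == control_group))
    stop("both target and control groups must be non-empty")
  sh <- sheet[keep, , drop = FALSE]
  Y <- meth[, match(sh$sample_id, colnames(meth)), drop = FALSE]
  if (any(is.na(colnames(Y)))) stop("sample sheet / matrix mismatch")
  n <- nrow(sh)
  grp <- as.numeric(sh$group == target_group)

  df <- data.frame(.group = grp)
  if (length(covariates)) {
    miss <- setdiff(covariates, names(sh))
    if (length(miss)) stop("covariates missing from sheet: ",
                           paste(miss, collapse = ", "))
    cov_df <- sh[covariates]
    cov_df[] <- lapply(cov_df, function(x) if (is.character(x)) factor(x) else x)
    if (anyNA(cov_df)) stop("covariates must be complete for retained samples")
    df <- cbind(df, cov_df)
  }
  X <- stats::model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    asn <- attr(X, "assign")[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    terms <- c("(Intercept)", colnames(df))[asn + 1]
    stop("covariate collinear with the design: ",
         paste(unique(terms), collapse = ", "))
  }

  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, t(Y))        # coefficients x probes
  E <- t(Y) - X %*% B                     # residuals, samples x probes
  dfree <- n - ncol(X)
  sigma2 <- colSums(E^2) / dfree
  gi <- which(colnames(X) == ".group")
  effect <- B[gi, ]
  se <- sqrt(sigma2 * XtXi[gi, gi])
  zero_var <- apply(Y, 1, function(r) stats::var(r) == 0)
  se[zero_var] <- NA_real_
  z <- effect / se
  p <- 2 * stats::pt(-abs(z), dfree)

  out <- data.frame(probe = rownames(meth), effect = effect, se = se,
                    z = z, p_nominal = p, z_adj = NA_real_, p_adj = NA_real_,
                    n = n, stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(probes)) {
    i <- match(out$probe, probes$probe_id)
    out$chrom <- probes$chrom[i]
    out$pos <- probes$pos[i]
    out <- out[c("probe", "chrom", "pos", "effect", "se", "z",
                 "p_nominal", "z_adj", "p_adj", "n")]
  }
  attr(out, "m_tests") <- sum(!zero_var)
  attr(out, "df") <- dfree
  attr(out, "contrast") <- c(target = target_group, control = control_group)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' @export
print.assoc_table <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat("MWAS association table: ", nrow(x), " probes, ",
      attr(x, "m_tests"), " valid tests (",
      ct["target"], " vs ", ct["control"], ", n = ", x$n[1], ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Genomic inflation factor
#'
#' Quantifies residual confounding in an association scan as the median
#' observed chi-square statistic divided by the null median of a 1-df
#' chi-square (0.4549364): `lambda = median(z^2) / qchisq(0.5, 1)`.
#'
#' @param z vector of z statistics, or `NULL` if `p` given.
#' @param p vector of two-sided p-values (converted via the chi-square
#'   quantile), used when `z` is `NULL`.
#' @return the inflation factor lambda.
#' @export
genomic_inflation <- function(z = NULL, p = NULL) {
  if (is.null(z) && is.null(p)) stop("supply z or p")
  chisq <- if (!is.null(z)) z^2 else stats::qchisq(p, df = 1, lower.tail = FALSE)
  chisq <- chisq[is.finite(chisq)]
  if (!length(chisq)) stop("empty input")
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Bonferroni significance threshold with display rounding
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m_tests number of tests.
#' @param signif_digits significant digits for the displayed threshold
#'   (3 for methylome-wide scans; summary tables often print 2).
#' @return list with `threshold` (exact alpha/m) and `display` (rounded
#'   half away from zero, the convention of printed significance levels:
#'   0.05/8 displays as 6.3e-3 at two significant digits).
#' @export
bonferroni_threshold <- function(alpha, m_tests, signif_digits = 3) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (m_tests < 1) stop("m_tests must be positive")
  thr <- alpha / m_tests
  list(threshold = thr, display = signif_half_up(thr, signif_digits))
}

# significant-figure rounding with halves away from zero
signif_half_up <- function(x, digits) {
  if (x == 0) return(0)
  e <- floor(log10(abs(x))) - digits + 1
  sign(x) * floor(abs(x) / 10^e + 0.5 + 1e-9) * 10^e
}

#' Call differentially methylated sites at a Bonferroni threshold
#'
#' @param assoc an `assoc_table` (adjusted p-values used when present,
#'   nominal otherwise).
#' @param alpha family-wise error rate.
#' @param m_tests number of tests for the Bonferroni correction; defaults to
#'   the table's valid-test count.
#' @return the subset of rows passing `p < alpha/m_tests`, with attributes
#'   `threshold` (exact) and `threshold_display` (3 significant figures).
#' @export
call_dms <- function(assoc, alpha = 0.05, m_tests = NULL) {
  p <- if (all(is.na(assoc$p_adj))) assoc$p_nominal else assoc$p_adj
  valid <- sum(!is.na(p))
  if (is.null(m_tests)) m_tests <- attr(assoc, "m_tests") %||% valid
  if (m_tests < valid) stop("m_tests smaller than the number of valid tests")
  bt <- bonferroni_threshold(alpha, m_tests, 3)
  out <- assoc[!is.na(p) & p < bt$threshold, , drop = FALSE]
  attr(out, "threshold") <- bt$threshold
  attr(out, "threshold_display") <- bt$display
  attr(out, "m_tests") <- m_tests
  class(out) <- c("assoc_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Conditional MWAS at one probe
#'
#' Re-fits a single probe's association model with a lead genetic variant's
#' dosage appended as a covariate, to ask how much of a group difference is
#' attributable to that variant's allele-frequency differentiation. Returns
#' the group effect before and after conditioning.
#'
#' @inheritParams run_mwas
#' @param probe_id probe to test.
#' @param lead_variant_dosage numeric dosage named by sample id (or aligned
#'   with `colnames(meth)`).
#' @return list with elements `before` and `after`, each
#'   `(effect, se, p)`.
#' @export
conditional_mwas <- function(meth, sheet, probe_id, lead_variant_dosage,
                             target_group, control_group, covariates = NULL) {
  keep <- sheet$group %in% c(target_group, control_group)
  sh <- sheet[keep, , drop = FALSE]
  y <- meth[probe_id, match(sh$sample_id, colnames(meth))]
  dos <- if (!is.null(names(lead_variant_dosage))) {
    lead_variant_dosage[sh$sample_id]
  } else {
    lead_variant_dosage[match(sh$sample_id, colnames(meth))]
  }
  if (anyNA(dos)) stop("dosage must be available for all samples in the two groups")
  if (stats::var(dos) == 0) stop("dosage is constant")
  grp <- as.numeric(sh$group == target_group)
  df <- data.frame(y = as.numeric(y), .group = grp)
  if (length(covariates)) df <- cbind(df, sh[covariates])
  fit1 <- stats::lm(y ~ ., data = df)
  df2 <- cbind(df, .dosage = as.numeric(dos))
  fit2 <- stats::lm(y ~ ., data = df2)
  pull <- function(fit) {
    co <- summary(fit)$coefficients[".group", ]
    list(effect = unname(co[1]), se = unname(co[2]), p = unname(co[4]))
  }
  list(before = pull(fit1), after = pull(fit2))
}

#' Sign asymmetry of DMS effects
#'
#' @param dms an `assoc_table` (or data.frame with an `effect` column).
#' @return list `(n_hyper, n_hypo, fraction_hyper)`; `fraction_hyper` is `NA`
#'   for an empty set.
#' @export
sign_asymmetry <- function(dms) {
  eff <- dms$effect
  if (length(eff) && any(eff == 0, na.rm = TRUE))
    stop("each DMS must have a nonzero effect")
  n_hyper <- sum(eff > 0, na.rm = TRUE)
  n_hypo <- sum(eff < 0, na.rm = TRUE)
  tot <- n_hyper + n_hypo
  list(n_hyper = n_hyper, n_hypo = n_hypo,
       fraction_hyper = if (tot == 0) NA_real_ else n_hyper / tot)
}

#' Greedy clumping of DMSs into quasi-independent representatives
#'
#' A documented simplification of co-methylation-region grouping: DMSs are
#' sorted by p-value; each in turn joins an existing clump if it lies on the
#' same chromosome, within `max_gap_bp` of the clump seed, and its beta
#' values correlate with the seed at `r^2 >=` the threshold; otherwise it
#' seeds a new clump. The clump seeds are the quasi-independent set.
#'
#' @param dms an `assoc_table` with `chrom` and `pos` columns.
#' @param meth probes x samples beta matrix covering the DMS probes.
#' @param r2_threshold squared-correlation threshold (default 0.2).
#' @param max_gap_bp maximum seed distance in bp (default 1000).
#' @return the rows of `dms` that seed clumps, with a `clump_size` column.
#' @export
clump_dms <- function(dms, meth, r2_threshold = 0.2, max_gap_bp = 1000) {
  if (nrow(dms) == 0) return(dms)
  if (is.null(dms$chrom) || is.null(dms$pos) || anyNA(dms$pos))
    stop("DMS probes must be annotated with chrom and pos")
  p <- if (all(is.na(dms$p_adj))) dms$p_nominal else dms$p_adj
  ord <- order(p)
  seeds <- integer(0)
  sizes <- integer(0)
  for (i in ord) {
    joined <- FALSE
    for (k in seq_along(seeds)) {
      s <- seeds[k]
      if (dms$chrom[i] == dms$chrom[s] &&
          abs(dms$pos[i] - dms$pos[s]) <= max_gap_bp) {
        r <- stats::cor(meth[dms$probe[i], ], meth[dms$probe[s], ])
        if (is.finite(r) && r^2 >= r2_threshold) {
          sizes[k] <- sizes[k] + 1L
          joined <- TRUE
          break
        }
      }
    }
    if (!joined) {
      seeds <- c(seeds, i)
      sizes <- c(sizes, 1L)
    }
  }
  out <- dms[seeds, , drop = FALSE]
  out$clump_size <- sizes
  out
}
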