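#' Covariate preadjustment and within-group rank-normalization
#'
#' Prepares methylation phenotypes for QTL mapping: per probe, takes OLS
#' residuals on the covariates, then applies the rank-based inverse normal
#' transformation ([rint()], Blom offset 3/8, average ranks for ties) within
#' each subgroup, and concatenates the groups.
#'
#' @param meth probes x samples beta matrix.
#' @param sheet sample sheet with `sample_id`, the grouping column and
#'   covariates.
#' @param covariates character vector of covariate column names (may be
#'   empty: residuals are then the centred values).
#' @param group_var name of the grouping column (default `"group"`).
#' @return probes x samples matrix of standardized residuals, columns in the
#'   input sample order.
#' @export
preadjust_and_rint <- function(meth, sheet, covariates = NULL,
                               group_var = "group") {
  sh <- sheet[match(colnames(meth), sheet$sample_id), , drop = FALSE]
  if (anyNA(sh$sample_id)) stop("sample sheet must cover all matrix columns")
  grp <- as.character(sh[[group_var]])
  sizes <- table(grp)
  if (any(sizes < 3)) stop("group with fewer than 3 samples")
  if (any(sizes < 10)) warning("group with fewer than 10 samples")

  if (length(covariates)) {
    df <- sh[covariates]
    df[] <- lapply(df, function(x) if (is.character(x)) factor(x) else x)
    if (anyNA(df)) stop("covariates must be complete")
    X <- stats::model.matrix(~ ., data = df)
    qx <- qr(X)
    resid <- t(qr.resid(qx, t(meth)))
  } else {
    resid <- meth - rowMeans(meth)
  }
  out <- resid
  for (g in unique(grp)) {
    cols <- which(grp == g)
    out[, cols] <- t(apply(resid[, cols, drop = FALSE], 1, rint))
  }
  dimnames(out) <- dimnames(meth)
  out
}

# marginal regression of each column of Y on each column of G is avoided;
# this computes b, se, p for one phenotype y against every column of G
marginal_assoc <- function(y, G) {
  n <- length(y)
  gc_ <- sweep(G, 2, colMeans(G))
  yc <- y - mean(y)
  sxx <- colSums(gc_^2)
  sxy <- as.numeric(crossprod(gc_, yc))
  b <- sxy / sxx
  syy <- sum(yc^2)
  rss <- syy - b * sxy
  rss[rss < 0] <- 0
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- b / se
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  list(b = b, se = se, p = p)
}

#' cis-meQTL mapping
#'
#' Tests every variant within `window_bp` of each probe (boundary closed:
#' a variant exactly `window_bp` away is included) by simple regression of
#' the standardized residual on the additive dosage. The per-probe lead is
#' the smallest nominal p, ties broken by smaller |distance| then
#' lexicographic variant id.
#'
#' @param residuals probes x samples matrix from [preadjust_and_rint()].
#' @param genotypes a `genotype_matrix` (dosage + variant annotation).
#' @param probes probe annotation data.frame (`probe_id`, `chrom`, `pos`).
#' @param window_bp cis window half-width (default 1 Mb).
#' @param nominal_threshold significance cut for reported records
#'   (default 1e-8).
#' @return list: `records` (pairs with `p_nominal <= threshold`... strictly
#'   `<`), `leads` (one row per mapped probe, `is_lead = TRUE`), `pairs`
#'   (all tested pairs), `skipped` (probes with no variant in window).
#'   Columns: probe_id, variant_id, distance_bp (variant - probe), b, se,
#'   p_nominal, is_lead.
#' @export
map_cis <- function(residuals, genotypes, probes, window_bp = 1e6,
                    nominal_threshold = 1e-8) {
  dos <- genotypes$dosage[colnames(residuals), , drop = FALSE]
  v <- genotypes$variants
  pr <- probes[match(rownames(residuals), probes$probe_id), ]
  out <- vector("list", nrow(pr))
  skipped <- character(0)
  for (i in seq_len(nrow(pr))) {
    win <- which(v$chrom == pr$chrom[i] & abs(v$pos - pr$pos[i]) <= window_bp)
    if (!length(win)) {
      skipped <- c(skipped, pr$probe_id[i])
      next
    }
    ma <- marginal_assoc(residuals[i, ], dos[, win, drop = FALSE])
    out[[i]] <- data.frame(
      probe_id = pr$probe_id[i], variant_id = v$variant_id[win],
      distance_bp = v$pos[win] - pr$pos[i],
      b = ma$b, se = ma$se, p_nominal = ma$p,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  pairs <- do.call(rbind, out)
  if (is.null(pairs))
    return(list(records = NULL, leads = NULL, pairs = NULL, skipped = skipped,
                nominal_threshold = nominal_threshold))
  pairs$is_lead <- FALSE
  lead_rows <- vapply(split(seq_len(nrow(pairs)), pairs$probe_id), function(ix) {
    sub <- pairs[ix, ]
    ix[order(sub$p_nominal, abs(sub$distance_bp), sub$variant_id)[1]]
  }, integer(1))
  pairs$is_lead[lead_rows] <- TRUE
  list(records = pairs[!is.na(pairs$p_nominal) &
                         pairs$p_nominal < nominal_threshold, ],
       leads = pairs[lead_rows, ],
       pairs = pairs, skipped = skipped,
       nominal_threshold = nominal_threshold)
}

#' Permutation calibration of a probe's top cis p-value
#'
#' Permutes the phenotype `n_perm` times, records the minimum nominal
#' p-value over the cis variants per permutation, fits a Beta(a, b) to the
#' minima by maximum likelihood (Newton from method-of-moments;
#' method-of-moments fallback with a warning on non-convergence), and
#' returns the beta-CDF-adjusted top p-value.
#'
#' @param residual_probe numeric phenotype vector (standardized residuals).
#' @param cis_genotypes samples x variants dosage matrix for the window
#'   (>= 2 variants recommended; 1 allowed).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed (a dedicated child seed is derived).
#' @return list of class `probe_perm_result`: p_top_nominal, beta_shape1,
#'   beta_shape2, p_adjusted, lead_index, null_min_p.
#' @export
permute_beta_adjust <- function(residual_probe, cis_genotypes,
                                n_perm = 1000L, seed = 1L) {
  G <- as.matrix(cis_genotypes)
  n <- length(residual_probe)
  stopifnot(nrow(G) == n)
  obs <- marginal_assoc(residual_probe, G)
  p_top <- min(obs$p)

  set.seed(child_seed(seed, 31L))
  perm_idx <- replicate(n_perm, sample.int(n))
  Yp <- matrix(residual_probe[perm_idx], n, n_perm)
  # correlation-based p: scale once, min over variants per permutation
  Gs <- scale(G)
  ok <- which(!is.na(colSums(Gs)) & apply(G, 2, stats::var) > 0)
  if (!length(ok)) stop("all cis variants monomorphic")
  Gs <- Gs[, ok, drop = FALSE]
  Ys <- scale(Yp)
  R <- crossprod(Ys, Gs) / (n - 1)
  R2 <- pmin(R^2, 1 - 1e-12)
  Tstat <- sqrt(R2 * (n - 2) / (1 - R2))
  Pm <- 2 * stats::pt(-Tstat, n - 2)
  null_min <- apply(Pm, 1, min)

  bf <- fit_beta_mle(null_min)
  structure(list(
    p_top_nominal = p_top,
    beta_shape1 = bf$shape1, beta_shape2 = bf$shape2,
    beta_converged = bf$converged,
    p_adjusted = stats::pbeta(p_top, bf$shape1, bf$shape2),
    lead_index = which.min(obs$p),
    null_min_p = null_min
  ), class = "probe_perm_result")
}

#' trans-meQTL mapping with a genome-wide permutation null
#'
#' Per probe, tests every variant outside the `exclusion_bp` window around
#' the probe (same chromosome) — variants on other chromosomes are always
#' tested. A single genome-wide null is built by permuting
#' `n_phenotype_samples` randomly selected probes once each and recording
#' each permutation's genome-wide minimum p; one Beta(a, b) is fitted to
#' those minima, and each probe's top nominal p is adjusted by its CDF.
#'
#' @inheritParams map_cis
#' @param exclusion_bp same-chromosome exclusion half-width (default 5 Mb).
#' @param nominal_threshold significance cut for records (default 1e-14).
#' @param n_phenotype_samples probes sampled for the null (default 1000;
#'   sampled with replacement, with a warning, if fewer probes exist).
#' @param seed integer seed.
#' @return list: `records`, `leads` (with p_adjusted), `null_beta`
#'   (shape1/shape2), `null_min_p`.
#' @export
map_trans <- function(residuals, genotypes, probes, exclusion_bp = 5e6,
                      nominal_threshold = 1e-14,
                      n_phenotype_samples = 1000L, seed = 1L) {
  dos <- genotypes$dosage[colnames(residuals), , drop = FALSE]
  v <- genotypes$variants
  pr <- probes[match(rownames(residuals), probes$probe_id), ]
  m <- nrow(pr)
  n <- ncol(residuals)

  trans_window <- function(i) {
    which(v$chrom != pr$chrom[i] | abs(v$pos - pr$pos[i]) > exclusion_bp)
  }

  out <- vector("list", m)
  leads <- vector("list", m)
  for (i in seq_len(m)) {
    win <- trans_window(i)
    if (!length(win)) next
    ma <- marginal_assoc(residuals[i, ], dos[, win, drop = FALSE])
    d <- data.frame(
      probe_id = pr$probe_id[i], variant_id = v$variant_id[win],
      distance_bp = ifelse(v$chrom[win] == pr$chrom[i],
                           v$pos[win] - pr$pos[i], NA_integer_),
      b = ma$b, se = ma$se, p_nominal = ma$p,
      stringsAsFactors = FALSE, row.names = NULL
    )
    lead <- order(d$p_nominal, abs(d$distance_bp), d$variant_id,
                  na.last = TRUE)[1]
    leads[[i]] <- d[lead, ]
    out[[i]] <- d[!is.na(d$p_nominal) & d$p_nominal < nominal_threshold, ]
  }

  # genome-wide permutation null
  set.seed(child_seed(seed, 32L))
  if (m < n_phenotype_samples) {
    warning("fewer probes than n_phenotype_samples; sampling with replacement")
    sel <- sample.int(m, n_phenotype_samples, replace = TRUE)
  } else {
    sel <- sample.int(m, n_phenotype_samples)
  }
  null_min <- vapply(sel, function(i) {
    win <- trans_window(i)
    if (!length(win)) return(NA_real_)
    y <- residuals[i, sample.int(n)]
    min(marginal_assoc(y, dos[, win, drop = FALSE])$p, na.rm = TRUE)
  }, numeric(1))
  null_min <- null_min[is.finite(null_min)]
  leads_df <- do.call(rbind, leads)
  bf <- if (length(null_min) >= 2 && !is.null(leads_df)) {
    fit_beta_mle(null_min)
  } else NULL
  if (!is.null(leads_df)) {
    leads_df$p_adjusted <- if (!is.null(bf)) {
      stats::pbeta(leads_df$p_nominal, bf$shape1, bf$shape2)
    } else NA_real_
  }
  records <- do.call(rbind, out)
  list(records = records, leads = leads_df,
       null_beta = if (!is.null(bf)) c(shape1 = bf$shape1, shape2 = bf$shape2),
       null_min_p = null_min, nominal_threshold = nominal_threshold)
}

#' FDR across probes
#'
#' Benjamini--Hochberg q-values by default, or Storey q-values with the
#' smoother pi0 estimate (natural spline of pi0(lambda) over a lambda grid,
#' evaluated at the largest lambda).
#'
#' @param p_adjusted vector of per-probe (beta-adjusted) p-values in [0, 1].
#' @param method `"BH"` (default) or `"storey"`.
#' @return q-values, same length as the input.
#' @export
fdr_across_probes <- function(p_adjusted, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (any(p_adjusted < 0 | p_adjusted > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  q_bh <- stats::p.adjust(p_adjusted, method = "BH")
  if (method == "BH") return(q_bh)
  lam <- seq(0.05, 0.95, 0.05)
  pi0_l <- vapply(lam, function(l) mean(p_adjusted > l, na.rm = TRUE) / (1 - l),
                  numeric(1))
  fit <- stats::smooth.spline(lam, pi0_l, df = 3)
  pi0 <- min(max(stats::predict(fit, x = max(lam))$y, 0), 1)
  if (pi0 <= 0) pi0 <- 1
  pmin(q_bh * pi0, 1)
}
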