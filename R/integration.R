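#' Standardize QTL effect sizes to the per-SD-per-allele scale
#'
#' Converts a z statistic, allele frequency and sample size into a
#' standardized effect and its standard error:
#' `b = z / sqrt(2 p (1-p) (n + z^2))`, `SE = 1 / sqrt(2 p (1-p) (n + z^2))`,
#' so effects from different datasets are comparable on one scale. The ratio
#' `b/SE` reproduces `z` exactly.
#'
#' @param z z statistics (b/SE on the original scale).
#' @param maf effect-allele (or minor-allele) frequencies in (0, 1).
#' @param n sample sizes.
#' @return data.frame with `b_std`, `se_std`, `z`, `maf`, `n`.
#' @export
standardize_effects <- function(z, maf, n) {
  if (any(maf <= 0 | maf >= 1)) stop("maf must lie strictly in (0, 1)")
  if (any(n <= 0)) stop("n must be positive")
  denom <- sqrt(2 * maf * (1 - maf) * (n + z^2))
  data.frame(b_std = z / denom, se_std = 1 / denom, z = z, maf = maf, n = n)
}

#' Correlation of QTL effects between two datasets, corrected for
#' estimation error
#'
#' Estimates the correlation of true effect sizes from two sets of estimated
#' effects and their standard errors (non-overlapping samples, error
#' covariance 0):
#' `r_b = cov(b1, b2) / sqrt((var(b1) - mean(se1^2)) (var(b2) - mean(se2^2)))`,
#' with a delete-one jackknife standard error over SNP-probe pairs.
#'
#' @param b1,se1 effects and standard errors in dataset 1.
#' @param b2,se2 effects and standard errors in dataset 2, aligned to the
#'   same SNP-probe pairs (alleles harmonized).
#' @return list: `r_b`, `se_jackknife`, `n_pairs`.
#' @export
rb_correlation <- function(b1, se1, b2, se2) {
  n <- length(b1)
  stopifnot(length(se1) == n, length(b2) == n, length(se2) == n)
  if (n < 3) stop("need at least 3 pairs")
  rb_stat <- function(b1, se1, b2, se2) {
    v1 <- stats::var(b1) - mean(se1^2)
    v2 <- stats::var(b2) - mean(se2^2)
    if (v1 <= 0 || v2 <= 0) stop("effect variance not identifiable: ",
                                 "variance term <= mean squared SE")
    stats::cov(b1, b2) / sqrt(v1 * v2)
  }
  est <- rb_stat(b1, se1, b2, se2)
  # vectorized delete-one jackknife via downdated sums
  s1 <- sum(b1); s2 <- sum(b2)
  s11 <- sum(b1^2); s22 <- sum(b2^2); s12 <- sum(b1 * b2)
  e1 <- sum(se1^2); e2 <- sum(se2^2)
  m <- n - 1
  mu1 <- (s1 - b1) / m; mu2 <- (s2 - b2) / m
  var1 <- (s11 - b1^2 - m * mu1^2) / (m - 1) - (e1 - se1^2) / m
  var2 <- (s22 - b2^2 - m * mu2^2) / (m - 1) - (e2 - se2^2) / m
  cov12 <- (s12 - b1 * b2 - m * mu1 * mu2) / (m - 1)
  loo <- cov12 / sqrt(var1 * var2)
  if (any(!is.finite(loo))) {
    # fall back to explicit recomputation where downdate degenerates
    bad <- which(!is.finite(loo))
    for (i in bad) {
      loo[i] <- tryCatch(
        rb_stat(b1[-i], se1[-i], b2[-i], se2[-i]), error = function(e) NA_real_)
    }
  }
  ok <- is.finite(loo)
  se_jk <- sqrt((sum(ok) - 1) / sum(ok) * sum((loo[ok] - mean(loo[ok]))^2))
  list(r_b = est, se_jackknife = se_jk, n_pairs = n)
}

#' Replication rate of significant QTL pairs
#'
#' Fraction of discovery-significant SNP-probe pairs whose replication
#' p-value passes the Bonferroni threshold `alpha / n_discovery` with a
#' matching effect sign.
#'
#' @param discovery data.frame with `variant_id`, `probe_id`, `b`.
#' @param replication data.frame with `variant_id`, `probe_id`, `b`, `p`.
#' @param alpha family-wise error rate for the replication test (default 0.05).
#' @return list: `rate`, `n_discovery`, `n_matched`, `n_replicated`.
#' @export
replication_rate <- function(discovery, replication, alpha = 0.05) {
  key_d <- paste(discovery$variant_id, discovery$probe_id)
  key_r <- paste(replication$variant_id, replication$probe_id)
  i <- match(key_d, key_r)
  matched <- !is.na(i)
  n_disc <- nrow(discovery)
  thr <- alpha / n_disc
  rep_ok <- matched & replication$p[i] < thr &
    sign(replication$b[i]) == sign(discovery$b)
  list(rate = sum(rep_ok, na.rm = TRUE) / n_disc,
       n_discovery = n_disc, n_matched = sum(matched),
       n_replicated = sum(rep_ok, na.rm = TRUE))
}

#' Summary-data-based Mendelian randomization test
#'
#' Tests whether a GWAS signal is mediated by a methylation probe using the
#' top meQTL as the instrument: `T = z_gwas^2 z_meqtl^2 / (z_gwas^2 +
#' z_meqtl^2)`, referred to a 1-df chi-square. Symmetric in its arguments
#' and bounded by `min(z_gwas^2, z_meqtl^2)`.
#'
#' @param z_gwas,z_meqtl z statistics for the variant in the GWAS and meQTL
#'   datasets (the instrument should pass 5e-8 in the meQTL data upstream).
#' @return list: `T_smr`, `p`.
#' @export
smr_test <- function(z_gwas, z_meqtl) {
  if (any(!is.finite(z_gwas)) || any(!is.finite(z_meqtl)))
    stop("z statistics must be finite")
  denom <- z_gwas^2 + z_meqtl^2
  T_smr <- ifelse(denom == 0, NA_real_, z_gwas^2 * z_meqtl^2 / denom)
  p <- ifelse(denom == 0, 1,
              stats::pchisq(T_smr, df = 1, lower.tail = FALSE))
  list(T_smr = T_smr, p = p)
}

#' Colocalization by approximate Bayes factors (single causal variant)
#'
#' Wakefield approximate Bayes factors are computed per variant from each
#' trait's effect and standard error with prior effect SD `sd_prior`
#' (0.15, the quantitative-trait default), and combined under the standard
#' five-hypothesis enumeration (H0 no association; H1/H2 one trait only;
#' H3 two distinct causal variants; H4 one shared causal variant) with
#' per-variant priors `p1`, `p2`, `p12`.
#'
#' @param stats1,stats2 data.frames with columns `SNP`, `b`, `se` (and
#'   optionally `A1`, `A2`, `freq` for harmonization via
#'   [harmonize_sumstats()]); variants are matched on `SNP`.
#' @param p1,p2,p12 prior probabilities (defaults 1e-4, 1e-4, 1e-5).
#' @param sd_prior prior SD of the true effect (default 0.15).
#' @return object of class `coloc_result`: posteriors `pp0`..`pp4`,
#'   `n_variants`, `priors`.
#' @export
coloc_abf <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      sd_prior = 0.15) {
  shared <- intersect(stats1$SNP, stats2$SNP)
  i1 <- match(shared, stats1$SNP)
  i2 <- match(shared, stats2$SNP)
  ok <- !is.na(stats1$se[i1]) & !is.na(stats2$se[i2]) &
    stats1$se[i1] > 0 & stats2$se[i2] > 0
  if (sum(ok) < 2) stop("need at least 2 shared variants with standard errors")
  i1 <- i1[ok]; i2 <- i2[ok]
  labf <- function(b, se) {
    v <- se^2
    w <- sd_prior^2
    r <- w / (w + v)
    0.5 * (log(1 - r) + (b / se)^2 * r)
  }
  l1 <- labf(stats1$b[i1], stats1$se[i1])
  l2 <- labf(stats2$b[i2], stats2$se[i2])
  lsum1 <- logsumexp(l1)
  lsum2 <- logsumexp(l2)
  lsum12 <- logsumexp(l1 + l2)
  # H3 sums over distinct pairs: log(exp(lsum1 + lsum2) - exp(lsum12))
  a <- lsum1 + lsum2
  b_ <- lsum12
  lh3 <- if (a > b_) a + log1p(-exp(b_ - a)) else -Inf
  lh <- c(h0 = 0,
          h1 = log(p1) + lsum1,
          h2 = log(p2) + lsum2,
          h3 = log(p1) + log(p2) + lh3,
          h4 = log(p12) + lsum12)
  pp <- exp(lh - logsumexp(lh))
  structure(list(pp0 = pp[["h0"]], pp1 = pp[["h1"]], pp2 = pp[["h2"]],
                 pp3 = pp[["h3"]], pp4 = pp[["h4"]],
                 n_variants = length(i1),
                 priors = c(p1 = p1, p2 = p2, p12 = p12)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization (single causal variant, ABF), ",
      x$n_variants, " variants\n", sep = "")
  pp <- unlist(x[c("pp0", "pp1", "pp2", "pp3", "pp4")])
  print(round(pp, 4))
  cat(if (x$pp4 > 0.8) "PP4 > 0.8: colocalization supported\n" else
    "PP4 <= 0.8: no colocalization claim\n")
  invisible(x)
}

#' Harmonize two summary-statistic tables on shared variants
#'
#' Matches records by variant id, flips `b` (and the frequency) in the
#' second dataset when its effect/other alleles are swapped relative to the
#' first, drops records with inconsistent allele pairs, and drops records
#' whose effect-allele frequencies differ by more than `diff_freq`
#' (mirroring a 0.2 allele-frequency concordance filter).
#'
#' @param stats1,stats2 data.frames with `SNP`, `A1`, `A2`, `freq`, `b`,
#'   `se`, `p`.
#' @param diff_freq maximum tolerated effect-allele frequency difference
#'   after harmonization (default 0.2).
#' @return list of the two aligned, harmonized data.frames.
#' @export
harmonize_sumstats <- function(stats1, stats2, diff_freq = 0.2) {
  shared <- intersect(stats1$SNP, stats2$SNP)
  s1 <- stats1[match(shared, stats1$SNP), ]
  s2 <- stats2[match(shared, stats2$SNP), ]
  same <- s1$A1 == s2$A1 & s1$A2 == s2$A2
  flipped <- s1$A1 == s2$A2 & s1$A2 == s2$A1
  s2$b[flipped] <- -s2$b[flipped]
  s2$freq[flipped] <- 1 - s2$freq[flipped]
  tmp <- s2$A1[flipped]
  s2$A1[flipped] <- s2$A2[flipped]
  s2$A2[flipped] <- tmp
  keep <- (same | flipped) & abs(s1$freq - s2$freq) <= diff_freq
  list(stats1 = s1[keep, ], stats2 = s2[keep, ],
       n_dropped = sum(!keep))
}

#' Association between group methylation differences and meQTL-predicted
#' differences
#'
#' If a site's group difference in mean methylation (`delta_y`) is driven by
#' allele-frequency differentiation (`delta_p`) of its meQTL variant with
#' effect `b`, then under additivity `delta_y` should track `2 delta_p b`.
#' Regresses `delta_y` on the predictor `2 delta_p b` across DMSs and
#' reports the slope, the Pearson correlation, and both two-sided p-values.
#'
#' @param delta_y per-DMS target-minus-control difference in mean DNAm.
#' @param delta_p per-DMS effect-allele frequency difference of the lead
#'   meQTL variant (same group orientation as `delta_y`).
#' @param b per-DMS meQTL effect of that variant.
#' @return object of class `diff_test_result`: slope, slope_se, p_slope,
#'   r, p_cor, n_dms, and the per-DMS predictor.
#' @export
differentiation_test <- function(delta_y, delta_p, b) {
  n <- length(delta_y)
  stopifnot(length(delta_p) == n, length(b) == n)
  if (n < 3) stop("need at least 3 DMSs")
  x <- 2 * delta_p * b
  fit <- stats::lm(delta_y ~ x)
  co <- summary(fit)$coefficients
  r <- stats::cor(delta_y, x)
  p_cor <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  structure(list(slope = unname(co["x", 1]), slope_se = unname(co["x", 2]),
                 p_slope = unname(co["x", 4]), r = r, p_cor = p_cor,
                 n_dms = n, predictor = x),
            class = "diff_test_result")
}

#' @export
print.diff_test_result <- function(x, ...) {
  cat(sprintf(
    "Differentiation test over %d DMSs:\n  slope %.3f (SE %.3f, p %.3g)\n  r %.3f (p %.3g)\n",
    x$n_dms, x$slope, x$slope_se, x$p_slope, x$r, x$p_cor))
  invisible(x)
}

#' Association of a phenotype with methylation at one probe
#'
#' OLS of the phenotype on the probe's beta value plus covariates
#' (default sex, age, residential site when present); the coefficient is
#' reported per unit beta value.
#'
#' @param meth probes x samples beta matrix.
#' @param sheet sample sheet including the phenotype and covariates.
#' @param probe_id probe to test.
#' @param phenotype name of the numeric phenotype column.
#' @param covariates covariate column names (default sex and age).
#' @return list: `beta`, `se`, `p`, `n`.
#' @export
probe_phenotype_association <- function(meth, sheet, probe_id, phenotype,
                                        covariates = c("sex", "age")) {
  y <- sheet[[phenotype]]
  if (!is.numeric(y)) stop("phenotype must be numeric")
  x <- as.numeric(meth[probe_id, match(sheet$sample_id, colnames(meth))])
  if (stats::var(x, na.rm = TRUE) == 0) stop("probe beta values are constant")
  keep <- !is.na(y) & !is.na(x)
  if (stats::var(y[keep]) == 0) stop("phenotype is constant")
  df <- data.frame(y = y[keep], .beta = x[keep])
  if (length(covariates)) df <- cbind(df, sheet[keep, covariates, drop = FALSE])
  fit <- stats::lm(y ~ ., data = df)
  co <- summary(fit)$coefficients[".beta", ]
  list(beta = unname(co[1]), se = unname(co[2]), p = unname(co[4]),
       n = sum(keep))
}
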