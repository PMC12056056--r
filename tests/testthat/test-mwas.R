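make_sheet <- function(n, groups) {
  data.frame(sample_id = sprintf("S%03d", seq_len(n)), group = groups,
             stringsAsFactors = FALSE)
}

test_that("indicator-only effect equals the raw group mean difference", {
  set.seed(1)
  n <- 40
  groups <- rep(c("AN", "NL"), each = n / 2)
  beta <- matrix(runif(5 * n, 0.2, 0.8), 5, n,
                 dimnames = list(paste0("cg", 1:5), sprintf("S%03d", 1:n)))
  beta[1, groups == "AN"] <- beta[1, groups == "AN"] - mean(beta[1, groups == "AN"]) + 0.6
  beta[1, groups == "NL"] <- beta[1, groups == "NL"] - mean(beta[1, groups == "NL"]) + 0.5
  a <- run_mwas(beta, make_sheet(n, groups), "AN", "NL")
  expect_equal(a$effect[1], 0.1, tolerance = 1e-12)
  raw_diff <- rowMeans(beta[, groups == "AN"]) - rowMeans(beta[, groups == "NL"])
  expect_equal(a$effect, unname(raw_diff), tolerance = 1e-12)
})

test_that("covariate-adjusted fit matches a hand-rolled normal-equations solve", {
  set.seed(42)
  n <- 30
  groups <- rep(c("AN", "NL"), each = 15)
  sheet <- make_sheet(n, groups)
  sheet$age <- round(runif(n, 20, 60))
  sheet$cellfrac <- runif(n)
  beta <- matrix(runif(5 * n, 0.3, 0.7), 5, n,
                 dimnames = list(paste0("cg", 1:5), sheet$sample_id))
  a <- run_mwas(beta, sheet, "AN", "NL", covariates = c("age", "cellfrac"))
  # oracle: explicit (X'X)^-1 X'y per probe
  X <- cbind(1, as.numeric(groups == "AN"), sheet$age, sheet$cellfrac)
  for (i in 1:5) {
    bhat <- solve(t(X) %*% X, t(X) %*% beta[i, ])
    res <- beta[i, ] - X %*% bhat
    s2 <- sum(res^2) / (n - ncol(X))
    se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
    tt <- bhat[2] / se
    expect_equal(a$effect[i], bhat[2], tolerance = 1e-10)
    expect_equal(a$se[i], se, tolerance = 1e-10)
    expect_equal(a$p_nominal[i], 2 * pt(-abs(tt), n - ncol(X)),
                 tolerance = 1e-10)
  }
})

test_that("null cohort gives nominal type-I error and lambda near 1", {
  co <- simulate_cohort(null_design(m_probes = 2000L))
  a <- run_mwas(co$beta, co$sheet, "AN", "NL",
                covariates = c("sex", "age", "batch", "CD4T", "CD8T", "NK",
                               "Bcell", "Mono"),
                probes = co$probes)
  expect_true(mean(a$p_nominal < 0.05) > 0.03 &&
                mean(a$p_nominal < 0.05) < 0.07)
  expect_lt(abs(genomic_inflation(z = a$z) - 1), 0.1)
})

test_that("collinear covariates and zero-variance probes are handled", {
  n <- 20
  groups <- rep(c("AN", "NL"), each = 10)
  sheet <- make_sheet(n, groups)
  sheet$same_as_group <- as.numeric(groups == "AN")
  beta <- matrix(runif(3 * n), 3, n,
                 dimnames = list(paste0("cg", 1:3), sheet$sample_id))
  expect_error(run_mwas(beta, sheet, "AN", "NL",
                        covariates = "same_as_group"), "collinear")
  beta[2, ] <- 0.5
  a <- run_mwas(beta, sheet, "AN", "NL")
  expect_true(is.na(a$se[2]))
  expect_equal(attr(a, "m_tests"), 2L)
  expect_error(run_mwas(beta, sheet, "AN", "XX"), "non-empty")
})

test_that("genomic inflation has the defining scale properties", {
  z <- rep(sqrt(qchisq(0.5, 1)), 100)
  expect_equal(genomic_inflation(z = z), 1)
  set.seed(2)
  z <- rnorm(5000)
  expect_equal(genomic_inflation(z = 2 * z), 4 * genomic_inflation(z = z))
  p <- runif(100000)
  expect_lt(abs(genomic_inflation(p = p) - 1), 0.02)
  expect_error(genomic_inflation(z = numeric(0)), "empty")
})

test_that("Bonferroni thresholds reproduce printed values under rounding", {
  expect_equal(bonferroni_threshold(0.05, 445001, 3)$display, 1.12e-7)
  expect_equal(bonferroni_threshold(0.05, 8)$threshold, 6.25e-3)
  expect_equal(bonferroni_threshold(0.05, 8, 2)$display, 6.3e-3)
  expect_equal(bonferroni_threshold(0.05, 32, 2)$display, 1.6e-3)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("DMS calling respects the threshold and is monotone in alpha", {
  a <- data.frame(probe = paste0("cg", 1:6), effect = rnorm(6), se = 1,
                  z = rnorm(6), p_nominal = c(1e-9, 0.02, 0.2, 1, 1e-8, 0.04),
                  p_adj = c(1e-9, 0.02, 0.2, 1, 1e-8, 0.04), z_adj = NA, n = 10)
  attr(a, "m_tests") <- 6L
  d1 <- call_dms(a, alpha = 0.05)
  expect_setequal(d1$probe, c("cg1", "cg5"))
  for (alpha in c(0.01, 0.001, 1e-4)) {
    expect_true(all(call_dms(a, alpha = alpha)$probe %in% d1$probe))
  }
  a$p_adj <- rep(1, 6)
  expect_equal(nrow(call_dms(a, alpha = 0.05)), 0)
  expect_error(call_dms(a, alpha = 0.05, m_tests = 2), "smaller")
})

test_that("sign asymmetry counts effects by sign", {
  r <- sign_asymmetry(data.frame(effect = c(1, 1, -1)))
  expect_equal(r$n_hyper, 2)
  expect_equal(r$n_hypo, 1)
  expect_equal(r$fraction_hyper, 2 / 3)
  r0 <- sign_asymmetry(data.frame(effect = numeric(0)))
  expect_true(is.na(r0$fraction_hyper))
  expect_error(sign_asymmetry(data.frame(effect = c(1, 0))), "nonzero")
})

test_that("simulated LTA sign asymmetry is recovered from called DMSs", {
  d <- sim_design(n_per_group = c(NH = 150L, AN = 120L, NL = 60L),
                  m_variants = 50L, m_probes = 1500L,
                  frac_dms_sta = 0, frac_dms_lta = 0.15,
                  sign_frac_hyper_lta = 0.8, dms_effect_size = 0.08,
                  frac_meqtl_probes = 0, age_effect_probes = 0L,
                  noise_sd = 0.25, seed = 31L)
  co <- simulate_cohort(d)
  a <- run_mwas(co$beta, co$sheet, "NH", "AN",
                covariates = c("sex", "age", "batch"), probes = co$probes)
  dms <- call_dms(a)
  expect_gt(nrow(dms), 50)
  r <- sign_asymmetry(dms)
  expect_lt(abs(r$fraction_hyper - 0.8), 0.08)
})

test_that("conditional analysis removes a fully dosage-driven group difference", {
  set.seed(5)
  n <- 120
  groups <- rep(c("NH", "AN"), each = n / 2)
  sheet <- make_sheet(n, groups)
  # differentiated dosage: NH enriched for alt allele
  dos <- c(rbinom(n / 2, 2, 0.7), rbinom(n / 2, 2, 0.3))
  beta <- matrix(0, 1, n, dimnames = list("cgX", sheet$sample_id))
  beta[1, ] <- 0.4 + 0.05 * dos # entirely dosage-driven, no noise
  r <- suppressWarnings(
    conditional_mwas(beta, sheet, "cgX", setNames(dos, sheet$sample_id),
                     "NH", "AN"))
  expect_gt(abs(r$before$effect), 0.01)
  expect_lt(abs(r$after$effect), 1e-8)
  expect_error(conditional_mwas(beta, sheet, "cgX",
                                setNames(rep(1, n), sheet$sample_id),
                                "NH", "AN"), "constant")
})

test_that("conditioning on group-independent dosage leaves the effect", {
  set.seed(6)
  n <- 200
  groups <- rep(c("NH", "AN"), each = n / 2)
  sheet <- make_sheet(n, groups)
  dos <- rbinom(n, 2, 0.4)
  beta <- matrix(0.5 + 0.03 * (groups == "NH") + 0.02 * dos + rnorm(n, 0, 0.02),
                 1, n, dimnames = list("cgX", sheet$sample_id))
  r <- conditional_mwas(beta, sheet, "cgX", setNames(dos, sheet$sample_id),
                        "NH", "AN")
  expect_lt(abs(r$after$effect - r$before$effect), 2 * r$before$se)
})

test_that("a half-mediated difference halves under conditioning", {
  set.seed(7)
  n <- 2000
  groups <- rep(c("NH", "AN"), each = n / 2)
  sheet <- make_sheet(n, groups)
  dos <- c(rbinom(n / 2, 2, 0.75), rbinom(n / 2, 2, 0.25))
  # direct group shift contributes 0.04; dosage pathway E[0.04*dos diff] = 0.04
  beta <- matrix(0.4 + 0.04 * (groups == "NH") + 0.04 * dos +
                   rnorm(n, 0, 0.03), 1, n,
                 dimnames = list("cgX", sheet$sample_id))
  r <- conditional_mwas(beta, sheet, "cgX", setNames(dos, sheet$sample_id),
                        "NH", "AN")
  expect_lt(abs(r$after$effect - 0.5 * r$before$effect), 2 * r$after$se)
})

test_that("clumping groups correlated neighbours and respects chromosomes", {
  co <- small_cohort()
  # two adjacent probes with identical beta vectors -> one representative
  beta <- co$beta[1:2, ]
  beta[2, ] <- beta[1, ]
  dms <- data.frame(probe = rownames(beta), chrom = "chr1", pos = c(100, 600),
                    effect = c(0.1, 0.1), se = 0.01, z = 10,
                    p_nominal = c(1e-10, 1e-9), p_adj = c(1e-10, 1e-9),
                    z_adj = 10, n = 100)
  out <- clump_dms(dms, beta)
  expect_equal(nrow(out), 1)
  expect_equal(out$probe, rownames(beta)[1]) # smaller p seeds the clump
  expect_equal(out$clump_size, 2L)
  # same vectors on different chromosomes never clump
  dms$chrom <- c("chr1", "chr2")
  expect_equal(nrow(clump_dms(dms, beta)), 2)
  dms$pos[1] <- NA
  expect_error(clump_dms(dms, beta), "annotated")
})

test_that("block-correlated DMSs reduce to one representative per block", {
  set.seed(13)
  n <- 60
  # two blocks of 10 probes: within-block pairwise r2 = 0.5 (loading
  # a = 0.5^(1/4), pairwise r = a^2 = sqrt(0.5)), between-block r2 = 0
  make_block <- function() {
    shared <- rnorm(n)
    a <- 0.5^0.25
    t(replicate(10, a * shared + sqrt(1 - a^2) * rnorm(n)))
  }
  beta <- rbind(make_block(), make_block())
  rownames(beta) <- sprintf("cg%02d", 1:20)
  colnames(beta) <- sprintf("S%03d", 1:n)
  dms <- data.frame(probe = rownames(beta), chrom = "chr1",
                    pos = c(seq(1000, 1900, 100), seq(2000, 2900, 100)),
                    effect = 0.1, se = 0.01, z = 10,
                    p_nominal = seq(1e-12, 1e-8, length.out = 20),
                    p_adj = seq(1e-12, 1e-8, length.out = 20),
                    z_adj = 10, n = n)
  out <- clump_dms(dms, beta, r2_threshold = 0.2, max_gap_bp = 2000)
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$clump_size), c(10L, 10L))
})
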