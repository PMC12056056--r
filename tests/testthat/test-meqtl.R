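test_that("RINT output has rank-normal properties and monotone invariance", {
  x0 <- c(3.2, -1, 0.5, 7, 2, 1.9, -4, 0.1, 9, -2.5, 1) # tie-free, odd n
  r <- rint(x0)
  expect_lt(abs(mean(r)), 1e-10) # symmetry of normal scores, odd n
  expect_equal(sd(r), 1, tolerance = 0.15)
  x <- c(x0[-6], 2) # with a tie
  expect_equal(rint(x), rint(exp(x))) # strictly monotone transform
  # ties share the averaged rank before the normal quantile
  rt <- rint(c(1, 1, 2))
  expect_equal(rt[1], rt[2])
  expect_equal(rt[1], qnorm((1.5 - 3 / 8) / (3 + 1 / 4)))
  expect_equal(rt[3], qnorm((3 - 3 / 8) / (3 + 1 / 4)))
})

test_that("preadjustment residualizes covariates and standardizes per group", {
  co <- small_cohort()
  covs <- c("sex", "age", "batch", "CD4T", "CD8T", "NK", "Bcell", "Mono")
  res <- preadjust_and_rint(co$beta, co$sheet, covs)
  expect_equal(dim(res), dim(co$beta))
  for (g in c("NH", "AN", "NL")) {
    cols <- co$sheet$group == g
    m <- rowMeans(res[1:20, cols])
    expect_true(all(abs(m) < 0.05))
    v <- apply(res[1:20, cols], 1, var)
    expect_true(all(abs(v - 1) < 0.15))
  }
  sh <- co$sheet
  sh$group <- as.character(sh$group)
  sh$group[1:3] <- "tiny"
  expect_error(suppressWarnings(preadjust_and_rint(co$beta[1:5, ], sh, NULL)),
               NA) # 3 samples allowed
  sh$group[1:2] <- "AN"
  expect_error(suppressWarnings(preadjust_and_rint(co$beta[1:5, ], sh, NULL)),
               "fewer than 3")
})

test_that("cis window boundary is closed at the window edge", {
  set.seed(20)
  n <- 50
  dosage <- matrix(rbinom(n * 3, 2, 0.4), n, 3,
                   dimnames = list(sprintf("S%03d", 1:n),
                                   c("snpA", "snpB", "snpC")))
  geno <- structure(list(
    dosage = dosage,
    variants = data.frame(variant_id = c("snpA", "snpB", "snpC"),
                          chrom = "chr1",
                          pos = c(2e6, 2e6 + 1e6, 2e6 + 1e6 + 1),
                          stringsAsFactors = FALSE)),
    class = "genotype_matrix")
  resid <- matrix(rnorm(n), 1, n,
                  dimnames = list("cg1", sprintf("S%03d", 1:n)))
  probes <- data.frame(probe_id = "cg1", chrom = "chr1", pos = 2e6)
  r <- map_cis(resid, geno, probes, window_bp = 1e6)
  expect_setequal(r$pairs$variant_id, c("snpA", "snpB")) # snpC is 1e6+1 away
  expect_equal(r$pairs$distance_bp[r$pairs$variant_id == "snpB"], 1e6)
})

test_that("a strong planted cis effect is detected at 1e-8", {
  detected <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 1400
    g <- rbinom(n, 2, 0.3)
    y <- rint(0.8 * (g - mean(g)) / sd(g) + rnorm(n))
    dosage <- cbind(snpA = g, snpB = rbinom(n, 2, 0.4))
    rownames(dosage) <- sprintf("S%04d", 1:n)
    geno <- structure(list(
      dosage = dosage,
      variants = data.frame(variant_id = c("snpA", "snpB"), chrom = "chr1",
                            pos = c(1e6, 1.5e6))), class = "genotype_matrix")
    resid <- matrix(y, 1, n, dimnames = list("cg1", rownames(dosage)))
    probes <- data.frame(probe_id = "cg1", chrom = "chr1", pos = 1.2e6)
    r <- map_cis(resid, geno, probes)
    r$leads$p_nominal < 1e-8 && r$leads$variant_id == "snpA"
  }, logical(1))
  expect_true(all(detected))
})

test_that("permuted phenotypes yield no cis records at 1e-8", {
  set.seed(21)
  n <- 300
  m <- 50
  dosage <- matrix(rbinom(n * 20, 2, 0.3), n, 20,
                   dimnames = list(sprintf("S%03d", 1:n),
                                   sprintf("snp%02d", 1:20)))
  geno <- structure(list(
    dosage = dosage,
    variants = data.frame(variant_id = colnames(dosage), chrom = "chr1",
                          pos = seq(1e6, 2e6, length.out = 20))),
    class = "genotype_matrix")
  resid <- matrix(rnorm(m * n), m, n,
                  dimnames = list(sprintf("cg%02d", 1:m), rownames(dosage)))
  probes <- data.frame(probe_id = rownames(resid), chrom = "chr1",
                       pos = round(seq(1.1e6, 1.9e6, length.out = m)))
  r <- map_cis(resid, geno, probes)
  expect_equal(nrow(r$records), 0)
  expect_equal(nrow(r$leads), m)
})

test_that("single-variant windows leave the top p essentially unadjusted", {
  set.seed(22)
  n <- 200
  g <- matrix(rbinom(n, 2, 0.4), n, 1)
  y <- rnorm(n)
  r <- permute_beta_adjust(y, g, n_perm = 500, seed = 23)
  # min of k=1 uniform is uniform: beta fit near Beta(1,1)
  expect_lt(abs(r$beta_shape1 - 1), 0.2)
  expect_lt(abs(r$p_adjusted - r$p_top_nominal), 0.05)
})

test_that("beta adjustment tracks correlated variants better than Bonferroni", {
  set.seed(24)
  n <- 300
  k <- 20
  shared <- rbinom(n, 2, 0.4)
  G <- vapply(1:k, function(j) {
    flip <- rbinom(n, 1, 0.1)
    ifelse(flip == 1, rbinom(n, 2, 0.4), shared)
  }, numeric(n)) # strongly correlated block
  y <- scale(shared + rnorm(n, 0, 1.2))[, 1]
  r <- permute_beta_adjust(y, G, n_perm = 1000, seed = 25)
  p_bonf <- min(1, r$p_top_nominal * k)
  expect_lt(r$p_adjusted, p_bonf)
  expect_lt(r$p_adjusted, 0.01)
  # monotone in the top nominal p for the same fitted null
  p_grid <- c(1e-8, 1e-6, 1e-4, 1e-2)
  adj <- pbeta(p_grid, r$beta_shape1, r$beta_shape2)
  expect_true(all(diff(adj) > 0))
})

test_that("trans exclusion zone and cross-chromosome testing are correct", {
  set.seed(26)
  n <- 80
  pos <- c(4.9e6, 5.1e6, 1e6)
  chrom <- c("chr1", "chr1", "chr2")
  dosage <- matrix(rbinom(n * 3, 2, 0.4), n, 3,
                   dimnames = list(sprintf("S%03d", 1:n),
                                   c("near", "far", "other")))
  geno <- structure(list(
    dosage = dosage,
    variants = data.frame(variant_id = colnames(dosage), chrom = chrom,
                          pos = pos)), class = "genotype_matrix")
  resid <- matrix(rnorm(2 * n), 2, n,
                  dimnames = list(c("cg1", "cg2"), rownames(dosage)))
  probes <- data.frame(probe_id = c("cg1", "cg2"), chrom = "chr1",
                       pos = c(10, 20))
  r <- suppressWarnings(map_trans(resid, geno, probes,
                                  n_phenotype_samples = 10, seed = 27))
  tested <- r$leads
  # variant 4.9 Mb away excluded, 5.1 Mb included, other chromosome included
  all_pairs <- expand.grid(probe = probes$probe_id,
                           variant = colnames(dosage))
  expect_false("near" %in% tested$variant_id &&
                 any(tested$variant_id == "near"))
  expect_true(all(tested$variant_id %in% c("far", "other")))
  expect_true(all(is.na(tested$distance_bp) |
                    abs(tested$distance_bp) > 5e6))
})

test_that("the (1 Mb, 5 Mb] annulus is assigned to neither cis nor trans", {
  set.seed(28)
  n <- 60
  dosage <- matrix(rbinom(n, 2, 0.4), n, 1,
                   dimnames = list(sprintf("S%03d", 1:n), "mid"))
  geno <- structure(list(
    dosage = dosage,
    variants = data.frame(variant_id = "mid", chrom = "chr1", pos = 3e6)),
    class = "genotype_matrix")
  resid <- matrix(rnorm(n), 1, n, dimnames = list("cg1", rownames(dosage)))
  probes <- data.frame(probe_id = "cg1", chrom = "chr1", pos = 10)
  cis <- map_cis(resid, geno, probes)
  expect_null(cis$pairs)
  expect_equal(cis$skipped, "cg1")
  tr <- suppressWarnings(map_trans(resid, geno, probes,
                                   n_phenotype_samples = 5, seed = 29))
  expect_null(tr$leads) # 3 Mb: inside the trans exclusion too
})

test_that("planted trans effect on another chromosome is recovered", {
  set.seed(30)
  n <- 1400
  g_trans <- rbinom(n, 2, 0.3)
  dosage <- cbind(trans_v = g_trans,
                  null_v = rbinom(n, 2, 0.4))
  rownames(dosage) <- sprintf("S%04d", 1:n)
  geno <- structure(list(
    dosage = dosage,
    variants = data.frame(variant_id = colnames(dosage),
                          chrom = c("chr2", "chr1"), pos = c(1e6, 8e6))),
    class = "genotype_matrix")
  y <- rint(1.0 * (g_trans - mean(g_trans)) / sd(g_trans) + rnorm(n))
  resid <- matrix(y, 1, n, dimnames = list("cg1", rownames(dosage)))
  probes <- data.frame(probe_id = "cg1", chrom = "chr1", pos = 10)
  r <- suppressWarnings(map_trans(resid, geno, probes,
                                  n_phenotype_samples = 20, seed = 31))
  expect_equal(nrow(r$records), 1)
  expect_equal(r$records$variant_id, "trans_v")
  expect_lt(r$records$p_nominal, 1e-14)
})

test_that("BH q-values match hand arithmetic and guard the null", {
  expect_equal(fdr_across_probes(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(fdr_across_probes(rep(1, 5)), rep(1, 5))
  set.seed(32)
  p <- runif(2000)
  expect_lt(mean(fdr_across_probes(p) < 0.05), 0.005)
  q_st <- fdr_across_probes(p, method = "storey")
  expect_true(all(q_st <= fdr_across_probes(p) + 1e-12))
  expect_error(fdr_across_probes(c(0.5, 2)), "lie in")
})

test_that("permutation adjustment is deterministic given the seed", {
  set.seed(33)
  n <- 150
  G <- matrix(rbinom(n * 5, 2, 0.3), n, 5)
  y <- rnorm(n)
  r1 <- permute_beta_adjust(y, G, n_perm = 200, seed = 9)
  r2 <- permute_beta_adjust(y, G, n_perm = 200, seed = 9)
  expect_identical(r1$p_adjusted, r2$p_adjusted)
  expect_identical(r1$null_min_p, r2$null_min_p)
})
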