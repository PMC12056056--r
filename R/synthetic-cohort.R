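#' Simulation design for a synthetic three-group high-altitude cohort
#'
#' Collects every generative parameter for the synthetic cohort: group sizes
#' for native highlanders (NH), acclimatized newcomers (AN) and native
#' lowlanders (NL), Tibetan-vs-Han allele-frequency differentiation, cis-meQTL
#' effects on methylation, group-specific mean-shift DMSs with asymmetric sign
#' fractions, age-correlated probes, and batch / cell-composition covariate
#' structure. Group sizes default to the post-QC cohort (687 NH, 299 AN,
#' 462 NL); matrix dimensions default to a desk-scale methylome.
#'
#' @param n_per_group named integer vector `c(NH=, AN=, NL=)`.
#' @param m_variants number of genetic variants.
#' @param m_probes number of DNAm probes.
#' @param maf_range ancestral allele-frequency range, within (0, 0.5].
#' @param fst differentiation parameter F in [0, 0.5): the pairwise Hudson
#'   Fst between the Tibetan (NH) and pooled Han (AN + NL) allele
#'   frequencies. The Tibetan frequency is drawn from a Balding--Nichols
#'   beta distribution around the shared ancestral frequency with drift
#'   parameter 2F (only one lineage drifts, so the pairwise Fst is half the
#'   drift parameter).
#' @param frac_dms_sta,frac_dms_lta fractions of probes carrying a
#'   short-term-acclimatization (AN-specific) or long-term-adaptation
#'   (NH-specific) mean shift.
#' @param sign_frac_hyper_sta,sign_frac_hyper_lta fraction of shifted probes
#'   with a positive (hypermethylation) shift. Defaults encode the observed
#'   asymmetry: STA predominantly hypomethylated (0.2), LTA predominantly
#'   hypermethylated (0.8).
#' @param dms_effect_size mean-shift magnitude on the beta-value scale.
#' @param frac_meqtl_probes fraction of probes with one causal cis variant.
#' @param meqtl_effect_sd SD of the per-allele causal effect on the latent
#'   (logit) scale.
#' @param age_effect_probes number of probes with an age slope.
#' @param age_slope_sd SD of the per-year latent age slope.
#' @param noise_sd residual SD on the latent scale.
#' @param batch_sd SD of per-probe-by-batch latent offsets.
#' @param cell_sd SD of per-probe loadings on (centred) cell fractions.
#' @param baseline_range optional `c(lo, hi)`: draw probe baselines uniformly
#'   in this interval instead of the default bimodal (array-like) mixture.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param seed master seed; stages derive child seeds via [child_seed()].
#' @return an object of class `sim_design` (a validated list).
#' @export
sim_design <- function(n_per_group = c(NH = 687L, AN = 299L, NL = 462L),
                       m_variants = 2000L,
                       m_probes = 10000L,
                       maf_range = c(0.05, 0.5),
                       fst = 0.1,
                       frac_dms_sta = 0.001,
                       frac_dms_lta = 0.01,
                       sign_frac_hyper_sta = 0.2,
                       sign_frac_hyper_lta = 0.8,
                       dms_effect_size = 0.05,
                       frac_meqtl_probes = 0.05,
                       meqtl_effect_sd = 0.5,
                       age_effect_probes = 200L,
                       age_slope_sd = 0.02,
                       noise_sd = 0.3,
                       batch_sd = 0.1,
                       cell_sd = 0.5,
                       baseline_range = NULL,
                       chrom_lengths = c(chr1 = 120e6, chr2 = 120e6),
                       seed = 1L) {
  d <- list(
    n_per_group = n_per_group, m_variants = as.integer(m_variants),
    m_probes = as.integer(m_probes), maf_range = maf_range, fst = fst,
    frac_dms_sta = frac_dms_sta, frac_dms_lta = frac_dms_lta,
    sign_frac_hyper_sta = sign_frac_hyper_sta,
    sign_frac_hyper_lta = sign_frac_hyper_lta,
    dms_effect_size = dms_effect_size,
    frac_meqtl_probes = frac_meqtl_probes,
    meqtl_effect_sd = meqtl_effect_sd,
    age_effect_probes = as.integer(age_effect_probes),
    age_slope_sd = age_slope_sd,
    noise_sd = noise_sd, batch_sd = batch_sd, cell_sd = cell_sd,
    baseline_range = baseline_range,
    chrom_lengths = chrom_lengths, seed = as.integer(seed)
  )
  fracs <- c(d$frac_dms_sta, d$frac_dms_lta, d$sign_frac_hyper_sta,
             d$sign_frac_hyper_lta, d$frac_meqtl_probes)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (d$maf_range[1] <= 0 || d$maf_range[2] > 0.5 ||
      d$maf_range[1] > d$maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (d$fst < 0 || d$fst >= 0.5)
    stop("fst must lie in [0, 0.5) (pairwise Fst with a single drifting lineage)")
  if (any(d$n_per_group < 0) || sum(d$n_per_group) == 0)
    stop("empty group: n_per_group must contain at least one sample")
  if (d$m_variants < 1 || d$m_probes < 1) stop("counts must be positive")
  if (!all(c("NH", "AN", "NL") %in% names(d$n_per_group)))
    stop("n_per_group must be named NH, AN, NL")
  structure(d, class = "sim_design")
}

#' Simulate group-differentiated genotypes
#'
#' Draws, per variant, an ancestral (Han) frequency p0 uniformly from
#' `maf_range`; the Tibetan (NH) frequency comes from the Balding--Nichols
#' beta distribution `Beta(p0(1-F)/F, (1-p0)(1-F)/F)` so that the expected
#' Fst between NH and the pooled Han groups equals F. AN and NL share the Han
#' frequency. Dosages are Binomial(2, group frequency); variants whose
#' empirical MAF falls below 0.01 are resampled. Variant positions are
#' uniform over the configured chromosomes.
#'
#' @param design a [sim_design()] object.
#' @return a list of class `genotype_matrix` with elements `dosage`
#'   (samples x variants), `variants` (data.frame: variant_id, chrom, pos,
#'   ref, alt, maf, freq_NH, freq_Han), and `labels` (group factor).
#' @export
simulate_genotypes <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(child_seed(design$seed, 1L))
  n <- design$n_per_group
  labels <- factor(rep(c("NH", "AN", "NL"), times = n[c("NH", "AN", "NL")]),
                   levels = c("NH", "AN", "NL"))
  N <- length(labels)
  m <- design$m_variants
  F <- design$fst

  # Only the Tibetan lineage drifts away from the shared ancestral (Han)
  # frequency, so a Balding--Nichols draw with drift parameter c yields a
  # realized Hudson Fst of c/2 between NH and the pooled Han groups. F is
  # defined as that pairwise Fst, hence c = 2F.
  cdrift <- 2 * F
  draw_variant <- function(k) {
    p0 <- stats::runif(k, design$maf_range[1], design$maf_range[2])
    if (F == 0) {
      p_nh <- p0
    } else {
      p_nh <- stats::rbeta(k, p0 * (1 - cdrift) / cdrift,
                           (1 - p0) * (1 - cdrift) / cdrift)
    }
    list(p0 = p0, p_nh = p_nh)
  }

  fr <- draw_variant(m)
  p0 <- fr$p0; p_nh <- fr$p_nh
  dos <- matrix(0L, N, m)
  is_nh <- labels == "NH"
  gen <- function(j) {
    g <- integer(N)
    g[is_nh] <- stats::rbinom(sum(is_nh), 2L, p_nh[j])
    g[!is_nh] <- stats::rbinom(sum(!is_nh), 2L, p0[j])
    g
  }
  for (j in seq_len(m)) dos[, j] <- gen(j)

  # resample variants that drifted to empirical MAF < 0.01
  for (iter in 1:50) {
    freq <- colMeans(dos) / 2
    bad <- which(pmin(freq, 1 - freq) < 0.01)
    if (!length(bad)) break
    fr <- draw_variant(length(bad))
    p0[bad] <- fr$p0; p_nh[bad] <- fr$p_nh
    for (i in seq_along(bad)) dos[, bad[i]] <- gen(bad[i])
  }

  chroms <- names(design$chrom_lengths)
  v_chr <- sample(chroms, m, replace = TRUE,
                  prob = design$chrom_lengths / sum(design$chrom_lengths))
  v_pos <- floor(stats::runif(m, 1, design$chrom_lengths[v_chr]))
  ord <- order(match(v_chr, chroms), v_pos)
  dos <- dos[, ord, drop = FALSE]
  p0 <- p0[ord]; p_nh <- p_nh[ord]; v_chr <- v_chr[ord]; v_pos <- v_pos[ord]
  freq <- colMeans(dos) / 2

  variants <- data.frame(
    variant_id = sprintf("snp%05d", seq_len(m)),
    chrom = v_chr, pos = as.integer(v_pos),
    ref = "A", alt = "G",
    maf = pmin(freq, 1 - freq),
    freq_NH = p_nh, freq_Han = p0,
    stringsAsFactors = FALSE
  )
  rownames(dos) <- sprintf("S%04d", seq_len(N))
  colnames(dos) <- variants$variant_id
  structure(list(dosage = dos, variants = variants, labels = labels),
            class = "genotype_matrix")
}

#' Simulate a methylome with known effect structure
#'
#' Generates beta values on the latent logit scale:
#' `latent = logit(baseline) + meQTL dosage effect + group shift + age slope
#' + batch offset + cell-fraction term + N(0, noise_sd)`, squashed through
#' the inverse logit. Group shifts are calibrated so that, absent noise and
#' other effects, the beta-scale group mean difference equals
#' `dms_effect_size` exactly. Returns the methylation matrix, a fully
#' populated sample sheet, probe annotations, and a truth table for
#' recovery tests.
#'
#' @param genotypes a `genotype_matrix` from [simulate_genotypes()].
#' @param design the same [sim_design()] used for the genotypes.
#' @return list of class `sim_cohort`: `beta` (probes x samples), `probes`
#'   (annotation data.frame), `sheet` (sample sheet), `truth` (per-probe truth
#'   data.frame), plus the inputs `dosage`, `variants`, `labels`.
#' @export
simulate_methylome <- function(genotypes, design) {
  stopifnot(inherits(design, "sim_design"), inherits(genotypes, "genotype_matrix"))
  set.seed(child_seed(design$seed, 2L))
  labels <- genotypes$labels
  N <- length(labels)
  m <- design$m_probes

  n_sta <- round(design$frac_dms_sta * m)
  n_lta <- round(design$frac_dms_lta * m)
  n_meqtl <- round(design$frac_meqtl_probes * m)
  n_age <- design$age_effect_probes
  if (n_sta + n_lta > m) stop("probe count smaller than requested DMS counts")
  if (n_age > m) stop("probe count smaller than requested age-probe count")

  # probe annotations: positions uniform, CpG-island relation, chromatin state
  chroms <- names(design$chrom_lengths)
  p_chr <- sample(chroms, m, replace = TRUE,
                  prob = design$chrom_lengths / sum(design$chrom_lengths))
  p_pos <- floor(stats::runif(m, 1, design$chrom_lengths[p_chr]))
  ord <- order(match(p_chr, chroms), p_pos)
  p_chr <- p_chr[ord]; p_pos <- p_pos[ord]
  cgi <- sample(c("island", "shore", "shelf", "open_sea"), m, replace = TRUE,
                prob = c(0.31, 0.23, 0.10, 0.36))
  states <- c("GapArtf", "Quies", "HET", "ReprPC", "Acet", "EnhWk", "EnhA",
              "TxEnh", "TxWk", "Tx", "TxEx", "znf", "DNase", "BivProm",
              "PromF", "TSS")
  state <- sample(states, m, replace = TRUE,
                  prob = c(1, 30, 6, 6, 4, 6, 4, 3, 12, 10, 3, 1, 4, 2, 4, 4))
  probes <- data.frame(
    probe_id = sprintf("cg%07d", seq_len(m)),
    chrom = p_chr, pos = as.integer(p_pos),
    cgi_relation = cgi, chrom_state = state,
    nearest_gene = sprintf("GENE%05d", sample.int(max(200L, m %/% 20), m, TRUE)),
    stringsAsFactors = FALSE
  )

  # baselines: bimodal array-like mixture unless a range is requested
  if (is.null(design$baseline_range)) {
    comp <- sample.int(3L, m, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    baseline <- ifelse(comp == 1L, stats::rbeta(m, 6, 54),
                ifelse(comp == 2L, stats::rbeta(m, 54, 6),
                       stats::rbeta(m, 10, 10)))
    baseline <- pmin(pmax(baseline, 0.02), 0.98)
  } else {
    baseline <- stats::runif(m, design$baseline_range[1], design$baseline_range[2])
  }

  # truth assignments (STA and LTA sets disjoint)
  idx <- sample.int(m, n_sta + n_lta)
  sta_idx <- idx[seq_len(n_sta)]
  lta_idx <- idx[n_sta + seq_len(n_lta)]
  shift_sign <- integer(m)
  shift_sign[sta_idx] <- ifelse(
    stats::runif(n_sta) < design$sign_frac_hyper_sta, 1L, -1L)
  shift_sign[lta_idx] <- ifelse(
    stats::runif(n_lta) < design$sign_frac_hyper_lta, 1L, -1L)
  shift_beta <- abs(shift_sign) * design$dms_effect_size

  meqtl_idx <- sample.int(m, n_meqtl)
  causal_variant <- rep(NA_character_, m)
  meqtl_effect <- rep(0, m)
  if (n_meqtl > 0) {
    v <- genotypes$variants
    for (i in meqtl_idx) {
      win <- which(v$chrom == p_chr[i] & abs(v$pos - p_pos[i]) <= 1e6)
      if (!length(win)) next # no variant close enough; probe stays meQTL-free
      causal_variant[i] <- v$variant_id[win[sample.int(length(win), 1L)]]
      meqtl_effect[i] <- stats::rnorm(1, 0, design$meqtl_effect_sd)
    }
  }
  age_idx <- sample.int(m, n_age)
  age_slope <- rep(0, m)
  age_slope[age_idx] <- stats::rnorm(n_age, 0, design$age_slope_sd)

  # sample sheet
  sex <- sample(c("F", "M"), N, replace = TRUE, prob = c(0.75, 0.25))
  age <- round(stats::runif(N, 18, 65))
  batch <- sample(paste0("B", 1:3), N, replace = TRUE)
  slide <- paste0("SL", sample.int(8L, N, replace = TRUE)) # not nested in batch
  s_row <- sample.int(6L, N, replace = TRUE)
  s_col <- sample.int(2L, N, replace = TRUE)
  cell_alpha <- c(CD4T = 9, CD8T = 6, NK = 3, Bcell = 3, Mono = 4, Gran = 30)
  cells <- matrix(stats::rgamma(N * 6, shape = rep(cell_alpha, each = N)), N, 6)
  cells <- cells / rowSums(cells)
  colnames(cells) <- names(cell_alpha)
  sheet <- data.frame(
    sample_id = rownames(genotypes$dosage),
    group = labels, sex = sex, age = age, batch = batch, slide = slide,
    sentrix_row = factor(s_row), sentrix_col = factor(s_col),
    cells, stringsAsFactors = FALSE
  )

  # latent matrix, probes x samples
  lat <- matrix(logit(baseline), m, N)
  # group shifts, calibrated on the beta scale: STA shifts the AN group,
  # LTA shifts the NH group
  delta_latent <- function(b0, s) logit(pmin(pmax(b0 + s, 0.01), 0.99)) - logit(b0)
  is_an <- labels == "AN"; is_nh <- labels == "NH"
  if (n_sta)
    lat[sta_idx, is_an] <- lat[sta_idx, is_an] +
      delta_latent(baseline[sta_idx], shift_sign[sta_idx] * shift_beta[sta_idx])
  if (n_lta)
    lat[lta_idx, is_nh] <- lat[lta_idx, is_nh] +
      delta_latent(baseline[lta_idx], shift_sign[lta_idx] * shift_beta[lta_idx])
  # cis-meQTL dosage effects
  has_qtl <- which(!is.na(causal_variant))
  if (length(has_qtl))
    lat[has_qtl, ] <- lat[has_qtl, ] + meqtl_effect[has_qtl] *
      t(genotypes$dosage[, causal_variant[has_qtl], drop = FALSE])
  # age slopes (centred so baselines stay interpretable)
  if (n_age)
    lat[age_idx, ] <- lat[age_idx, ] +
      outer(age_slope[age_idx], age - mean(age))
  # batch offsets and cell-fraction loadings
  if (design$batch_sd > 0) {
    boff <- matrix(stats::rnorm(m * 3, 0, design$batch_sd), m, 3,
                   dimnames = list(NULL, paste0("B", 1:3)))
    lat <- lat + boff[, batch]
  }
  if (design$cell_sd > 0) {
    cload <- matrix(stats::rnorm(m * 6, 0, design$cell_sd), m, 6)
    lat <- lat + cload %*% t(scale(cells, scale = FALSE))
  }
  if (design$noise_sd > 0)
    lat <- lat + matrix(stats::rnorm(m * N, 0, design$noise_sd), m, N)

  beta <- inv_logit(lat)
  rownames(beta) <- probes$probe_id
  colnames(beta) <- sheet$sample_id

  truth <- data.frame(
    probe_id = probes$probe_id,
    baseline = baseline,
    is_sta_dms = seq_len(m) %in% sta_idx,
    is_lta_dms = seq_len(m) %in% lta_idx,
    shift_sign = shift_sign,
    shift_beta = shift_beta,
    causal_variant = causal_variant,
    meqtl_effect = meqtl_effect,
    is_age_probe = seq_len(m) %in% age_idx,
    age_slope = age_slope,
    stringsAsFactors = FALSE
  )
  structure(list(beta = beta, probes = probes, sheet = sheet, truth = truth,
                 dosage = genotypes$dosage, variants = genotypes$variants,
                 labels = labels, design = design),
            class = "sim_cohort")
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper running [simulate_genotypes()] then
#' [simulate_methylome()].
#'
#' @inheritParams simulate_genotypes
#' @return a `sim_cohort` list; see [simulate_methylome()].
#' @export
simulate_cohort <- function(design) {
  simulate_methylome(simulate_genotypes(design), design)
}

#' Simulate a pair of summary-statistic sets over one region
#'
#' Simulates two quantitative phenotypes on the same genotypes — with either a
#' shared causal variant or two distinct causal variants — and returns
#' per-variant marginal association summary statistics for each, as fixtures
#' for colocalization and SMR analyses.
#'
#' @param genotypes a `genotype_matrix`.
#' @param region variant ids (or column indices) defining the region.
#' @param causal_variant_shared logical; if `TRUE` both traits share one
#'   causal variant, otherwise two distinct variants are chosen.
#' @param n1,n2 sample sizes for the two traits (rows are recycled by
#'   resampling if larger than the genotype matrix).
#' @param effect1,effect2 per-allele effects in phenotype-SD units.
#' @param seed integer seed.
#' @return list of two `data.frame`s in COJO-style columns
#'   (SNP, A1, A2, freq, b, se, p, N) plus the causal variant ids.
#' @export
simulate_sumstats_pair <- function(genotypes, region,
                                   causal_variant_shared = TRUE,
                                   n1 = 2000L, n2 = 2000L,
                                   effect1 = 0.5, effect2 = 0.5,
                                   seed = 1L) {
  set.seed(child_seed(seed, 3L))
  dos <- genotypes$dosage
  if (is.numeric(region)) region <- colnames(dos)[region]
  if (length(region) < 2L) stop("region must contain at least 2 variants")
  G <- dos[, region, drop = FALSE]
  if (any(apply(G, 2, stats::sd) == 0)) stop("monomorphic region")

  pick_rows <- function(n) {
    if (n <= nrow(G)) seq_len(n) else sample.int(nrow(G), n, replace = TRUE)
  }
  causal1 <- sample(region, 1L)
  causal2 <- if (causal_variant_shared) causal1 else {
    sample(setdiff(region, causal1), 1L)
  }

  one_trait <- function(n, causal, eff) {
    rows <- pick_rows(n)
    g <- G[rows, , drop = FALSE]
    y <- eff * g[, causal] + stats::rnorm(n)
    freq <- colMeans(g) / 2
    b <- se <- p <- numeric(ncol(g))
    for (j in seq_len(ncol(g))) {
      x <- g[, j]
      vx <- stats::var(x)
      if (vx == 0) { b[j] <- 0; se[j] <- NA; p[j] <- 1; next }
      bj <- stats::cov(x, y) / vx
      res <- y - mean(y) - bj * (x - mean(x))
      s2 <- sum(res^2) / (n - 2)
      sej <- sqrt(s2 / (vx * (n - 1)))
      b[j] <- bj; se[j] <- sej
      p[j] <- 2 * stats::pt(-abs(bj / sej), n - 2)
    }
    v <- genotypes$variants
    vi <- match(colnames(g), v$variant_id)
    data.frame(SNP = colnames(g), A1 = v$alt[vi], A2 = v$ref[vi],
               freq = freq, b = b, se = se, p = p, N = n,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  list(stats1 = one_trait(n1, causal1, effect1),
       stats2 = one_trait(n2, causal2, effect2),
       causal1 = causal1, causal2 = causal2)
}

#' Beta value from methylated/unmethylated intensities
#'
#' Converts array intensities to a methylation beta value with the offset-100
#' convention: `beta = M / (M + U + 100)`.
#'
#' @param M methylated intensity (>= 0), vectorized.
#' @param U unmethylated intensity (>= 0), vectorized.
#' @return beta values in [0, 1).
#' @export
beta_from_intensities <- function(M, U) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  M / (M + U + 100)
}
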