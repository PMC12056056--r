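#' Matched resampling null sets for probe enrichment
#'
#' Draws `n_resamples` null probe sets from the background, each matching the
#' query set's composition exactly on the CpG-island relation strata
#' (island / shore / shelf / open sea) — the standard discretization of
#' "matched distances to CpG islands". Sampling is without replacement
#' within each stratum.
#'
#' @param set_probes character vector of query probe ids.
#' @param background_probes character vector of background probe ids
#'   (all tested probes; must contain the set).
#' @param match_key named character vector probe id -> stratum label.
#' @param n_resamples number of null sets (default 1000).
#' @param seed integer seed.
#' @return list of `n_resamples` character vectors, each a null probe set
#'   with the query's per-stratum counts.
#' @export
matched_probe_null <- function(set_probes, background_probes, match_key,
                               n_resamples = 1000L, seed = 1L) {
  strata_set <- match_key[set_probes]
  strata_bg <- match_key[background_probes]
  if (anyNA(strata_set) || anyNA(strata_bg))
    stop("match_key must cover all set and background probes")
  counts <- table(strata_set)
  by_stratum <- split(background_probes, strata_bg)
  for (s in names(counts)) {
    if (length(by_stratum[[s]]) < counts[[s]])
      stop("stratum '", s, "' has fewer background probes (",
           length(by_stratum[[s]]), ") than required (", counts[[s]], ")")
  }
  set.seed(child_seed(seed, 21L))
  lapply(seq_len(n_resamples), function(i) {
    unlist(lapply(names(counts), function(s) {
      pool <- by_stratum[[s]]
      pool[sample.int(length(pool), counts[[s]])]
    }), use.names = FALSE)
  })
}

#' Enrichment of a probe set in annotation categories against resampled nulls
#'
#' For each category (e.g. each of the 16 chromatin states) computes the
#' odds ratio of membership in the query set versus the background and a
#' permutation p-value from matched null sets, with the add-one rule
#' `p = (1 + #{null >= observed}) / (n_resamples + 1)`.
#'
#' @param set_probes query probe ids.
#' @param annotation named character vector probe id -> category label,
#'   covering set and background.
#' @param null_sets list of null probe sets from [matched_probe_null()].
#' @param background_probes background probe ids (odds-ratio denominator).
#' @param two_sided if `TRUE`, doubles the smaller permutation tail
#'   (capped at 1); default one-sided enrichment.
#' @return data.frame (class `enrichment_result`) with one row per category:
#'   category, observed, expected, odds_ratio, ci95_lo, ci95_hi, p_perm,
#'   n_resamples.
#' @export
element_enrichment <- function(set_probes, annotation, null_sets,
                               background_probes, two_sided = FALSE) {
  if (anyNA(annotation[set_probes]) || anyNA(annotation[background_probes]))
    stop("annotation must cover all probes")
  cats <- sort(unique(annotation[background_probes]))
  n_res <- length(null_sets)
  n_set <- length(set_probes)
  n_bg <- length(background_probes)
  set_tab <- table(factor(annotation[set_probes], levels = cats))
  bg_tab <- table(factor(annotation[background_probes], levels = cats))
  null_counts <- vapply(null_sets, function(ns)
    as.integer(table(factor(annotation[ns], levels = cats))),
    integer(length(cats)))
  if (length(cats) == 1L) null_counts <- matrix(null_counts, nrow = 1L)

  rows <- lapply(seq_along(cats), function(k) {
    obs <- as.integer(set_tab[k])
    in_bg <- as.integer(bg_tab[k])
    nulls <- null_counts[k, ]
    expected <- mean(nulls)
    odds_set <- obs / (n_set - obs)
    odds_bg <- in_bg / (n_bg - in_bg)
    or <- if (in_bg == 0L || !is.finite(odds_set) || odds_bg == 0) NA_real_
          else odds_set / odds_bg
    p_hi <- (1 + sum(nulls >= obs)) / (n_res + 1)
    p_lo <- (1 + sum(nulls <= obs)) / (n_res + 1)
    p <- if (two_sided) min(1, 2 * min(p_hi, p_lo)) else p_hi
    ci <- stats::quantile(nulls, c(0.025, 0.975), names = FALSE)
    data.frame(category = cats[k], observed = obs, expected = expected,
               odds_ratio = or, ci95_lo = ci[1], ci95_hi = ci[2],
               p_perm = p, n_resamples = n_res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Trait-catalog overlap enrichment by Fisher's exact test
#'
#' Tests, per trait, whether the query probes overlap catalog-annotated
#' probes (e.g. an EWAS-catalog extract for gestational age, birth weight,
#' smoking, ...) more than expected, via a one-sided Fisher's exact test on
#' the 2x2 table (in set x in trait) over the background. The reported odds
#' ratio is the sample odds ratio.
#'
#' @param set_probes query probe ids (non-empty).
#' @param catalog named list trait -> character vector of probe ids, or a
#'   data.frame with columns `probe` and `trait`.
#' @param background_probes all tested probe ids.
#' @return data.frame: trait, n_set_in, n_bg_in, odds_ratio, p.
#' @export
trait_overlap_enrichment <- function(set_probes, catalog, background_probes) {
  if (!length(set_probes)) stop("empty probe set")
  if (is.data.frame(catalog)) catalog <- split(catalog$probe, catalog$trait)
  out_set <- setdiff(background_probes, set_probes)
  rows <- lapply(names(catalog), function(tr) {
    in_trait <- intersect(catalog[[tr]], background_probes)
    a <- length(intersect(set_probes, in_trait))
    b <- length(set_probes) - a
    c_ <- length(intersect(out_set, in_trait))
    d <- length(out_set) - c_
    or <- if (b == 0L || c_ == 0L) {
      if (a == 0L || d == 0L) NA_real_ else Inf
    } else (a * d) / (b * c_)
    p <- if (c_ + d == 0L || b + d == 0L) 1 else
      stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                         alternative = "greater")$p.value
    data.frame(trait = tr, n_set_in = a, n_bg_in = a + c_,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' MAF-matched enrichment of lead variants in GWAS signal
#'
#' Compares the proportion of lead variants with a GWAS p-value below the
#' threshold against `n_resamples` sets of randomly sampled variants matched
#' on minor-allele-frequency bins (default 50 equal-width bins on [0, 0.5]).
#'
#' @param lead_variants character vector of lead variant ids.
#' @param gwas_p named numeric vector variant id -> GWAS p-value, covering
#'   leads and candidates.
#' @param variant_maf named numeric vector variant id -> MAF.
#' @param p_threshold GWAS significance cut (default 1e-5).
#' @param n_bins number of equal-width MAF bins (default 50).
#' @param n_resamples,seed resampling controls.
#' @return list: `fold` (observed / mean null proportion, `Inf` guarded),
#'   `p_perm` (add-one permutation p), `observed_prop`, `null_props`.
#' @export
maf_matched_variant_enrichment <- function(lead_variants, gwas_p, variant_maf,
                                           p_threshold = 1e-5, n_bins = 50L,
                                           n_resamples = 1000L, seed = 1L) {
  if (anyNA(variant_maf[lead_variants]) || anyNA(gwas_p[lead_variants]))
    stop("leads must have MAF and GWAS p")
  bins <- cut(variant_maf, breaks = seq(0, 0.5, length.out = n_bins + 1),
              include.lowest = TRUE)
  names(bins) <- names(variant_maf)
  lead_bins <- bins[lead_variants]
  counts <- table(droplevels(lead_bins))
  candidates <- setdiff(names(variant_maf), lead_variants)
  by_bin <- split(candidates, bins[candidates])
  for (b in names(counts)) {
    if (length(by_bin[[b]]) < counts[[b]])
      stop("MAF bin ", b, " has too few candidate variants")
  }
  obs <- mean(gwas_p[lead_variants] < p_threshold)
  set.seed(child_seed(seed, 22L))
  null_props <- vapply(seq_len(n_resamples), function(i) {
    draw <- unlist(lapply(names(counts), function(b) {
      pool <- by_bin[[b]]
      pool[sample.int(length(pool), counts[[b]])]
    }), use.names = FALSE)
    mean(gwas_p[draw] < p_threshold)
  }, numeric(1))
  mean_null <- mean(null_props)
  fold <- if (mean_null == 0) {
    if (obs == 0) NA_real_ else Inf
  } else obs / mean_null
  p_perm <- (1 + sum(null_props >= obs)) / (n_resamples + 1)
  list(fold = fold, p_perm = p_perm, observed_prop = obs,
       null_props = null_props)
}

#' Enrichment of variants in chromosome-end (telomere/subtelomere) windows
#'
#' Fold enrichment of variants falling within `end_window_bp` of either end
#' of each chromosome, relative to the genomic fraction those windows cover,
#' with a bootstrap confidence interval over variants.
#'
#' @param variants data.frame with `chrom` and `pos` (1-based).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param end_window_bp window size at each chromosome end (default 1 Mb).
#' @param n_boot bootstrap replicates for the CI (default 1000).
#' @param seed integer seed.
#' @return list: `fold`, `ci95` (bootstrap percentile CI), `observed_frac`,
#'   `genome_frac`.
#' @export
positional_enrichment <- function(variants, chrom_lengths,
                                  end_window_bp = 1e6, n_boot = 1000L,
                                  seed = 1L) {
  if (any(chrom_lengths <= 2 * end_window_bp))
    stop("chromosome lengths must exceed twice the end window")
  len <- chrom_lengths[variants$chrom]
  in_end <- variants$pos <= end_window_bp | variants$pos > len - end_window_bp
  genome_frac <- sum(2 * end_window_bp * length(chrom_lengths)) /
    sum(chrom_lengths)
  obs <- mean(in_end)
  fold <- obs / genome_frac
  set.seed(child_seed(seed, 23L))
  n <- length(in_end)
  boot <- vapply(seq_len(n_boot), function(i)
    mean(in_end[sample.int(n, n, replace = TRUE)]) / genome_frac, numeric(1))
  list(fold = fold, ci95 = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
       observed_frac = obs, genome_frac = genome_frac)
}
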