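#' Validate cohort inputs for analysis
#'
#' Checks sample-id concordance across the genotype matrix, methylation
#' matrix and sample sheet; beta-value range; duplicated probe/variant ids;
#' and chromosome naming consistency. Returns a report rather than erroring,
#' so callers can surface every problem at once.
#'
#' @param meth probes x samples beta matrix.
#' @param sheet sample sheet data.frame.
#' @param genotypes optional `genotype_matrix`.
#' @param probes optional probe annotation data.frame.
#' @return data.frame of failures (empty when everything is concordant) with
#'   columns `check` and `detail`.
#' @export
validate_inputs <- function(meth, sheet, genotypes = NULL, probes = NULL) {
  fail <- list()
  note <- function(check, detail)
    fail[[length(fail) + 1L]] <<- data.frame(check = check, detail = detail,
                                             stringsAsFactors = FALSE)
  extra_sheet <- setdiff(sheet$sample_id, colnames(meth))
  extra_meth <- setdiff(colnames(meth), sheet$sample_id)
  if (length(extra_sheet))
    note("sample_concordance", paste("in sheet but not methylation:",
                                     paste(extra_sheet, collapse = ",")))
  if (length(extra_meth))
    note("sample_concordance", paste("in methylation but not sheet:",
                                     paste(extra_meth, collapse = ",")))
  bad <- which(meth < 0 | meth > 1, arr.ind = TRUE)
  if (nrow(bad))
    for (i in seq_len(min(nrow(bad), 20L)))
      note("beta_range", sprintf("beta=%.3g at probe %s sample %s",
                                 meth[bad[i, 1], bad[i, 2]],
                                 rownames(meth)[bad[i, 1]],
                                 colnames(meth)[bad[i, 2]]))
  if (anyDuplicated(rownames(meth)))
    note("duplicate_probes", paste(unique(rownames(meth)[duplicated(rownames(meth))]),
                                   collapse = ","))
  if (!is.null(genotypes)) {
    if (anyDuplicated(colnames(genotypes$dosage)))
      note("duplicate_variants", "duplicated variant ids in dosage matrix")
    extra_g <- setdiff(rownames(genotypes$dosage), sheet$sample_id)
    if (length(extra_g))
      note("sample_concordance", paste("in genotypes but not sheet:",
                                       paste(extra_g, collapse = ",")))
    if (!is.null(probes)) {
      cv <- unique(genotypes$variants$chrom)
      cp <- unique(probes$chrom)
      if (!length(intersect(cv, cp)))
        note("chrom_naming", sprintf("no shared chromosome names (%s vs %s)",
                                     paste(cv, collapse = ","),
                                     paste(cp, collapse = ",")))
    }
  }
  if (!length(fail))
    return(data.frame(check = character(0), detail = character(0)))
  do.call(rbind, fail)
}

#' Assemble a pipeline run configuration
#'
#' @param out_dir output directory for stage results and the manifest.
#' @param design a [sim_design()] for the simulate stage (or `NULL` when
#'   supplying data directly to [run_pipeline()]).
#' @param covariates MWAS/meQTL covariate columns.
#' @param alpha family-wise error rate for DMS calling.
#' @param cis_window_bp,cis_nominal_threshold cis mapping parameters.
#' @param n_perm permutations per probe for beta-adjusted cis significance.
#' @param n_perm_probes cap on probes taken through per-probe permutation
#'   (the most significant leads are taken first).
#' @param n_enrich_resamples matched resampling count for enrichment.
#' @param run_trans whether to run the trans scan.
#' @param clock_model_path optional clock JSON; when `NULL` a ridge clock is
#'   trained on the cohort.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       design = sim_design(),
                       covariates = c("sex", "age", "batch", "slide",
                                      "sentrix_row", "sentrix_col",
                                      "CD4T", "CD8T", "NK", "Bcell", "Mono"),
                       alpha = 0.05,
                       cis_window_bp = 1e6,
                       cis_nominal_threshold = 1e-8,
                       n_perm = 200L,
                       n_perm_probes = 20L,
                       n_enrich_resamples = 200L,
                       run_trans = FALSE,
                       clock_model_path = NULL,
                       seed = 1L) {
  if (!is.null(clock_model_path) && !file.exists(clock_model_path))
    stop("clock_model_path does not exist: ", clock_model_path)
  structure(list(out_dir = out_dir, design = design, covariates = covariates,
                 alpha = alpha, cis_window_bp = cis_window_bp,
                 cis_nominal_threshold = cis_nominal_threshold,
                 n_perm = n_perm, n_perm_probes = n_perm_probes,
                 n_enrich_resamples = n_enrich_resamples,
                 run_trans = run_trans, clock_model_path = clock_model_path,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out_dir <- NULL # identical analyses hash alike wherever they are written
  yaml::write_yaml(rapply(cfg, unclass, how = "replace"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes: simulate (when no cohort supplied) -> MWAS STA (AN vs NL) ->
#' MWAS LTA (NH vs AN), each with empirical-null correction and Bonferroni
#' DMS calling -> chromatin-state enrichment of the LTA DMSs against matched
#' nulls -> cis-meQTL mapping with permutation-calibrated leads -> the
#' differentiation test of group methylation differences against
#' meQTL-predicted differences -> epigenetic clock age-acceleration tests.
#' Every stage writes a TSV/JSON output carrying the config hash, and a
#' manifest records seeds, parameters, and row counts.
#'
#' @param config a [run_config()].
#' @param cohort optional pre-built `sim_cohort` (skips the simulate stage).
#' @return list with the per-stage results and the manifest, invisibly.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  manifest <- list(package_version = as.character(utils::packageVersion("altiwas")),
                   seed = config$seed, config_hash = hash, stages = list())
  t_all <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed [ALTIWAS_STAGE_ERROR]: ",
           conditionMessage(e), call. = FALSE))
    manifest$stages[[name]]$seconds <<-
      round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    res
  }

  if (is.null(cohort)) {
    cohort <- stage("simulate", simulate_cohort(config$design))
    write_cohort(cohort, file.path(config$out_dir, "cohort"))
  }
  manifest$stages$simulate$n_probes <- nrow(cohort$beta)
  manifest$stages$simulate$n_samples <- ncol(cohort$beta)

  rep_validate <- stage("validate", validate_inputs(
    cohort$beta, cohort$sheet,
    structure(list(dosage = cohort$dosage, variants = cohort$variants),
              class = "genotype_matrix"),
    cohort$probes))
  if (nrow(rep_validate)) {
    write_tsv_table(rep_validate, file.path(config$out_dir, "validation.tsv"),
                    hash)
    stop("stage 'validate' failed [ALTIWAS_STAGE_ERROR]: ",
         nrow(rep_validate), " input checks failed (see validation.tsv)")
  }

  one_mwas <- function(label, target, control) {
    assoc <- run_mwas(cohort$beta, cohort$sheet, target, control,
                      covariates = config$covariates, probes = cohort$probes)
    ba <- bacon_adjust(assoc$z[!is.na(assoc$z)], df = attr(assoc, "df"),
                       seed = config$seed)
    assoc$z_adj[!is.na(assoc$z)] <- ba$z_adj
    assoc$p_adj[!is.na(assoc$z)] <- ba$p_adj
    dms <- call_dms(assoc, alpha = config$alpha)
    write_tsv_table(assoc, file.path(config$out_dir,
                                     paste0("mwas_", label, ".tsv")), hash)
    jsonlite::write_json(
      list(bias = ba$fit$bias, inflation = ba$fit$inflation,
           weights = ba$fit$weights, means = ba$fit$means, sds = ba$fit$sds,
           lambda_before = genomic_inflation(z = assoc$z),
           lambda_after = genomic_inflation(z = assoc$z_adj)),
      file.path(config$out_dir, paste0("bacon_", label, ".json")),
      auto_unbox = TRUE, digits = NA)
    manifest$stages[[paste0("mwas_", label)]]$n_dms <<- nrow(dms)
    list(assoc = assoc, bacon = ba$fit, dms = dms)
  }
  sta <- stage("mwas_sta", one_mwas("sta", "AN", "NL"))
  lta <- stage("mwas_lta", one_mwas("lta", "NH", "AN"))

  enr <- stage("enrichment", {
    dms_ids <- lta$dms$probe
    if (length(dms_ids) >= 5) {
      match_key <- stats::setNames(cohort$probes$cgi_relation,
                                   cohort$probes$probe_id)
      anno <- stats::setNames(cohort$probes$chrom_state,
                              cohort$probes$probe_id)
      nulls <- matched_probe_null(dms_ids, cohort$probes$probe_id, match_key,
                                  n_resamples = config$n_enrich_resamples,
                                  seed = config$seed)
      res <- element_enrichment(dms_ids, anno, nulls, cohort$probes$probe_id)
      write_tsv_table(res, file.path(config$out_dir, "enrichment_lta.tsv"),
                      hash)
      res
    } else NULL
  })

  geno <- structure(list(dosage = cohort$dosage, variants = cohort$variants),
                    class = "genotype_matrix")
  cis <- stage("meqtl_cis", {
    resid <- preadjust_and_rint(cohort$beta, cohort$sheet,
                                covariates = config$covariates)
    res <- map_cis(resid, geno, cohort$probes,
                   window_bp = config$cis_window_bp,
                   nominal_threshold = config$cis_nominal_threshold)
    write_tsv_table(res$leads, file.path(config$out_dir, "meqtl_cis_leads.tsv"),
                    hash)
    # permutation-calibrated significance for the strongest leads
    top <- utils::head(res$leads[order(res$leads$p_nominal), ],
                       config$n_perm_probes)
    perm <- lapply(seq_len(nrow(top)), function(k) {
      pid <- top$probe_id[k]
      i <- match(pid, cohort$probes$probe_id)
      win <- which(cohort$variants$chrom == cohort$probes$chrom[i] &
                     abs(cohort$variants$pos - cohort$probes$pos[i]) <=
                     config$cis_window_bp)
      pr <- permute_beta_adjust(resid[pid, ],
                                cohort$dosage[colnames(resid), win, drop = FALSE],
                                n_perm = config$n_perm,
                                seed = child_seed(config$seed, 31L, i))
      data.frame(probe_id = pid, p_top_nominal = pr$p_top_nominal,
                 beta_shape1 = pr$beta_shape1, beta_shape2 = pr$beta_shape2,
                 p_adjusted = pr$p_adjusted, stringsAsFactors = FALSE)
    })
    perm_df <- do.call(rbind, perm)
    if (!is.null(perm_df)) {
      perm_df$q_value <- fdr_across_probes(perm_df$p_adjusted)
      write_tsv_table(perm_df, file.path(config$out_dir, "meqtl_cis_perm.tsv"),
                      hash)
    }
    c(res, list(perm = perm_df, residuals = resid))
  })
  manifest$stages$meqtl_cis$n_records <-
    if (is.null(cis$records)) 0L else nrow(cis$records)

  trans <- if (config$run_trans) stage("meqtl_trans", {
    res <- map_trans(cis$residuals, geno, cohort$probes, seed = config$seed)
    write_tsv_table(res$leads, file.path(config$out_dir, "meqtl_trans_leads.tsv"),
                    hash)
    res
  }) else NULL

  diff <- stage("differentiation", {
    dms_ids <- lta$dms$probe
    leads <- cis$leads
    ok <- dms_ids[dms_ids %in% leads$probe_id]
    if (length(ok) >= 3) {
      li <- match(ok, leads$probe_id)
      vi <- match(leads$variant_id[li], cohort$variants$variant_id)
      is_nh <- cohort$labels == "NH"; is_an <- cohort$labels == "AN"
      delta_y <- rowMeans(cohort$beta[ok, is_nh, drop = FALSE]) -
        rowMeans(cohort$beta[ok, is_an, drop = FALSE])
      dp <- colMeans(cohort$dosage[is_nh, leads$variant_id[li], drop = FALSE]) / 2 -
        colMeans(cohort$dosage[is_an, leads$variant_id[li], drop = FALSE]) / 2
      # meQTL effect on the beta-value scale, same scale as delta_y
      b_beta <- vapply(seq_along(ok), function(k)
        marginal_assoc(cohort$beta[ok[k], ],
                       cohort$dosage[, leads$variant_id[li[k]], drop = FALSE])$b,
        numeric(1))
      res <- differentiation_test(delta_y, dp, b_beta)
      write_tsv_table(
        data.frame(probe_id = ok, delta_y = delta_y, delta_p = dp, b = b_beta,
                   predictor = res$predictor),
        file.path(config$out_dir, "differentiation.tsv"), hash)
      res
    } else NULL
  })

  clk <- stage("clock", {
    ages <- cohort$sheet$age
    model <- if (!is.null(config$clock_model_path)) {
      read_clock_json(config$clock_model_path)
    } else {
      train_clock(cohort$beta, ages, seed = config$seed)
    }
    pred <- apply_clock(model, cohort$beta)
    aar <- compute_aar(pred, ages, cohort$sheet$group)
    tests <- group_aar_tests(aar)
    write_tsv_table(aar, file.path(config$out_dir, "aar.tsv"), hash)
    write_tsv_table(tests$pairwise, file.path(config$out_dir,
                                              "aar_pairwise.tsv"), hash)
    r2 <- vapply(split(seq_along(pred), as.character(cohort$sheet$group)),
                 function(ix) r2_accuracy(pred[ix], ages[ix]), numeric(1))
    list(model = model, aar = aar, tests = tests, r2_by_group = r2)
  })

  manifest$total_seconds <- round(as.numeric(
    difftime(Sys.time(), t_all, units = "secs")), 2)
  manifest$parameters <- list(
    alpha = config$alpha, cis_window_bp = config$cis_window_bp,
    cis_nominal_threshold = config$cis_nominal_threshold,
    n_perm = config$n_perm, n_enrich_resamples = config$n_enrich_resamples)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(cohort = cohort, sta = sta, lta = lta, enrichment = enr,
                 cis = cis, trans = trans, differentiation = diff,
                 clock = clk, manifest = manifest))
}
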