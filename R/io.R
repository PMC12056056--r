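#' Write and read tab-separated matrices and tables
#'
#' Dosage and methylation matrices are written with a header row of sample
#' ids and row names in the first column; tables are plain TSV. All writers
#' prepend `# config_hash: <hash>` comment lines when a hash is supplied, so
#' outputs are traceable to the configuration that produced them.
#'
#' @param x matrix or data.frame.
#' @param path output path.
#' @param config_hash optional hash string recorded as a header comment.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(x, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash: ", config_hash), con)
  df <- data.frame(id = rownames(x), as.data.frame(x, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname write_tsv_matrix
#' @export
write_tsv_table <- function(x, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash: ", config_hash), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write genotypes as a minimal VCF with dosage (DS) and genotype (GT) fields
#'
#' @param genotypes a `genotype_matrix`.
#' @param path output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  dos <- genotypes$dosage
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dos)), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    g <- dos[, j]
    cells <- paste0(gt_code[round(g) + 1L], ":", format(g, trim = TRUE))
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref[j],
                       v$alt[j], ".", "PASS", ".", "GT:DS", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF (DS preferred, GT fallback)
#'
#' Requires the vcfR package.
#'
#' @param path `.vcf` (optionally gzipped) path.
#' @return a `genotype_matrix` (without group labels).
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- tryCatch(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]))
    })
  }
  fix <- vcfR::getFIX(vcf)
  dosage <- t(ds)
  colnames(dosage) <- fix[, "ID"]
  freq <- colMeans(dosage, na.rm = TRUE) / 2
  variants <- data.frame(
    variant_id = fix[, "ID"], chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]), ref = fix[, "REF"], alt = fix[, "ALT"],
    maf = pmin(freq, 1 - freq), stringsAsFactors = FALSE
  )
  structure(list(dosage = dosage, variants = variants, labels = NULL),
            class = "genotype_matrix")
}

#' Read / write COJO-style summary statistics (.ma)
#'
#' Tab- or space-separated with header `SNP A1 A2 freq b se p N`.
#'
#' @param path file path.
#' @return for the reader, a data.frame in the `.ma` column order.
#' @export
read_sumstats_ma <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "N")
  if (!all(need %in% names(df)))
    stop(".ma file must have columns: ", paste(need, collapse = " "))
  df[need]
}

#' @rdname read_sumstats_ma
#' @param stats data.frame with columns SNP, A1, A2, freq, b, se, p, N.
#' @export
write_sumstats_ma <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' Emits dosage TSV, VCF, methylation TSV, sample sheet, probe annotation,
#' truth table, and the design as YAML.
#'
#' @param cohort a `sim_cohort` from [simulate_methylome()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno <- structure(list(dosage = cohort$dosage, variants = cohort$variants,
                         labels = cohort$labels), class = "genotype_matrix")
  write_tsv_matrix(cohort$dosage, file.path(dir, "dosage.tsv"))
  write_vcf(geno, file.path(dir, "genotypes.vcf"))
  write_tsv_matrix(cohort$beta, file.path(dir, "methylation.tsv"))
  write_tsv_table(cohort$sheet, file.path(dir, "sample_sheet.tsv"))
  write_tsv_table(cohort$probes, file.path(dir, "probes.tsv"))
  write_tsv_table(cohort$variants, file.path(dir, "variants.tsv"))
  write_tsv_table(cohort$truth, file.path(dir, "truth.tsv"))
  d <- cohort$design
  d$n_per_group <- as.list(d$n_per_group)
  d$chrom_lengths <- as.list(d$chrom_lengths)
  yaml::write_yaml(unclass(d), file.path(dir, "design.yaml"))
  invisible(dir)
}
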