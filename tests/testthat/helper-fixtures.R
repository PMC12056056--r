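# Shared fixtures, built in code: a small three-group cohort with known
# signal structure, reused across module tests.

small_design <- function(...) {
  sim_design(n_per_group = c(NH = 80L, AN = 60L, NL = 70L),
             m_variants = 300L, m_probes = 400L,
             frac_dms_sta = 0.02, frac_dms_lta = 0.05,
             age_effect_probes = 40L, seed = 11L, ...)
}

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(small_design())
    cache
  }
})

# a null cohort: no DMS, no meQTL, no age signal (covariate structure stays)
null_design <- function(m_probes = 400L, seed = 7L, ...) {
  sim_design(n_per_group = c(NH = 80L, AN = 60L, NL = 70L),
             m_variants = 200L, m_probes = m_probes,
             frac_dms_sta = 0, frac_dms_lta = 0, frac_meqtl_probes = 0,
             age_effect_probes = 0L, seed = seed, ...)
}

expect_tsv_roundtrip <- function(mat) {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  write_tsv_matrix(mat, f)
  back <- read_tsv_matrix(f)
  expect_equal(back, mat, tolerance = 1e-12)
}
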