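Package: altiwas
Title: Methylome-Wide Association and meQTL Analysis of High-Altitude Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for methylome-wide association studies (MWAS) of
    high-altitude acclimatization and adaptation: covariate-adjusted per-probe
    association with empirical-null (bias/inflation) correction of test
    statistics, Bonferroni calling of differentially methylated sites,
    enrichment against matched resampling nulls, cis/trans meQTL mapping with
    permutation-calibrated beta-distribution-adjusted significance, cross-dataset
    effect-size correlation (r_b with jackknife errors), summary-based Mendelian
    randomization and approximate-Bayes-factor colocalization with GWAS summary
    statistics, a genetic-differentiation test for adaptation-associated sites,
    and epigenetic-clock age-acceleration analysis. Includes a synthetic-cohort
    generator emulating the three-group highlander/newcomer/lowlander design so
    every stage is exercisable without access-restricted individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
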