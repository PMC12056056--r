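---
title: "Methods: methylome-wide association and meQTL analysis of high-altitude adaptation"
author: "altiwas authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylome-wide association and meQTL analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific setting

altiwas implements a methylome-wide analysis of high-altitude
acclimatization and adaptation in a three-group design: native highlanders
(NH, highland Tibetans), acclimatized newcomers (AN, Han Chinese who moved
to high altitude), and native lowlanders (NL, lowland Han). Contrasting AN
against NL isolates the epigenetic response to short-term acclimatization
(STA); contrasting NH against AN isolates long-term adaptation (LTA) on top
of acclimatization. The package covers the full analysis chain — per-probe
association scans with empirical-null correction, enrichment against
matched resampling nulls, cis/trans meQTL mapping with permutation-calibrated
significance, summary-statistic integration (r~b~, SMR, colocalization), a
genetic-differentiation test, and epigenetic-clock age-acceleration
analysis — together with a synthetic-cohort generator, because the
individual-level data of such cohorts are access-restricted.

# The association model

For each DNAm probe $i$ the scan fits, by ordinary least squares,

$$\mathrm{DNAm}_i \sim \text{group} + \text{sex} + \text{age} +
  \text{batch} + \text{array position} + \text{cell composition},$$

where group is an indicator (target = 1, control = 0). The reported effect
is the group coefficient: the covariate-adjusted difference in mean beta
value between target and control. Beta values are modeled directly (not
M-values); the effect therefore reads as a methylation-fraction difference,
which is the scale on which results are reported. Because all probes share
one design matrix, the scan is computed as a single multi-response
least-squares solve.

Test statistics are reported as $z = \hat\beta/\mathrm{se}$; with $n$ in the
hundreds these are t statistics with large residual degrees of freedom, and
p-values use the t reference (the `df` argument of `bacon_adjust()`), which
matters only in the far tail used for methylome-wide calling.

## Empirical-null correction

Residual confounding inflates or shifts the null distribution of $z$.
`bacon_adjust()` estimates that null as the dominant component of a
three-component Gaussian mixture — a null component plus one signal
component on each side — and rescales $z_\mathrm{adj} = (z - \hat b)/\hat\sigma$.
Two implementation choices matter:

* **Fitting.** The mixture is fitted by EM with deterministic random
  restarts rather than a Gibbs sampler: the estimand (location and scale of
  the null component) is identical, and convergence control is simpler. The
  statistics are binned (up to 2000 bins) before fitting, which leaves the
  estimates unchanged at methylome scale and makes each EM pass cheap. The
  fit is affine-equivariant to machine precision.
* **Identifiability.** On signal-free input an unconstrained three-component
  mixture is unidentifiable — signal components slowly absorb the null. The
  signal component means are therefore constrained to lie at least
  `sep_sd = 2` null-SDs from the null mean (and to be at least as dispersed
  as the null). At this separation the null-scale estimate attains the
  efficiency of a plain Gaussian MLE on pure-null data (standard error
  ~0.007 at $n = 10^4$), while genuine methylome-wide signals — which sit
  many null-SDs out — are still absorbed by the signal components.
  Signals closer than 2 null-SDs to the null mean are treated as null;
  this is the price of a stable null estimate and is shared, in one form
  or another, by every empirical-null method.

The inflation factor $\lambda = \mathrm{median}(z^2)/0.4549$ quantifies
calibration before and after adjustment. Differentially methylated sites
(DMSs) are called at the Bonferroni threshold $\alpha/m$; displayed
thresholds round half away from zero (so $0.05/8$ prints as
$6.3\times10^{-3}$), matching the convention of printed significance levels.

## Sign asymmetry, clumping, conditional analysis

`sign_asymmetry()` summarizes the direction of DMS effects (the two
contrasts are expected to skew in opposite directions: STA predominantly
hypomethylated, LTA predominantly hypermethylated). `clump_dms()` reduces
DMSs to quasi-independent representatives by a greedy rule — sort by p,
join an existing clump when on the same chromosome within `max_gap_bp`
(default 1 kb) of the seed and correlated at $r^2 \ge 0.2$ — a documented
simplification of co-methylation-region construction, which builds regions
from background correlation instead. `conditional_mwas()` refits one probe
with a lead variant's dosage as a covariate; the drop in the group effect
measures how much of the difference that variant's frequency
differentiation explains.

# Enrichment against constructed nulls

Probe-set enrichment draws 1000 null sets matched *exactly* on the
CpG-island relation (island / shore / shelf / open sea — the standard
discretization of distance to CpG islands), and compares observed category
counts to the null distribution with the add-one permutation p-value
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n+1)$, which can never be zero.
One-sided enrichment is the default direction, with a two-sided option that
doubles the smaller tail. Odds ratios are sample odds ratios; trait-catalog
overlap uses the one-sided Fisher exact test. Variant-level enrichment
matches on 50 equal-width MAF bins over $[0, 0.5]$; positional enrichment
compares the variant fraction in 1 Mb chromosome-end windows to the genomic
fraction those windows occupy, with a bootstrap CI over variants.

# meQTL mapping

Methylation phenotypes are first residualized on the covariates, then
rank-inverse-normal transformed (RINT, Blom offset 3/8, average ranks for
ties) *within each group*, and the groups concatenated — standardizing
within group before merging, so group mean differences cannot masquerade as
genetic effects.

* **cis**: every variant within 1 Mb of the probe (boundary closed at
  exactly 1 Mb; positions 1-based) is tested by simple regression on
  dosage; the genome-wide nominal threshold is $10^{-8}$. The per-probe
  lead is the smallest p, ties broken by distance then variant id.
* **Permutation calibration**: the probe's phenotype is permuted 1000
  times; each permutation's minimum p over the cis window is recorded; a
  Beta(a, b) is fitted to the minima by Newton-from-method-of-moments MLE
  (method-of-moments fallback with a warning), and the observed top p is
  adjusted through its CDF. This accounts for the number *and correlation*
  of cis variants — the adjusted p is smaller than Bonferroni-times-k when
  variants are in LD. Across probes, adjusted p-values get BH (default) or
  Storey q-values.
* **trans**: all variants beyond 5 Mb from the probe (or on other
  chromosomes) at nominal $10^{-14}$; the permutation null is built once,
  genome-wide, from 1000 randomly selected probes permuted once each. The
  (1 Mb, 5 Mb] annulus is deliberately assigned to neither map.

Each probe's permutations use a dedicated child seed (`child_seed()`, a
fixed multiplicative-hash counter scheme), so any single probe can be
re-run in isolation and reproduce the full-run result bit for bit.

# Integration of summary statistics

Effects from different datasets are standardized to the per-SD-per-allele
scale, $\hat b = z/\sqrt{2p(1-p)(n+z^2)}$ with
$\mathrm{SE} = 1/\sqrt{2p(1-p)(n+z^2)}$, so $\hat b/\mathrm{SE}$ reproduces
$z$ exactly. The correlation of true effects between datasets is estimated
by $r_b = \mathrm{cov}(b_1,b_2)\big/\sqrt{(\mathrm{var}(b_1)-\overline{se_1^2})
(\mathrm{var}(b_2)-\overline{se_2^2})}$ with a delete-one jackknife SE
(computed by down-dated sums, so the 1000-pair jackknife is vectorized).
The error-covariance term is set to zero — appropriate for non-overlapping
cohorts, which is the cross-dataset use here; overlapping-sample correction
is out of scope.

SMR tests mediation with the top meQTL as instrument:
$T = z_1^2 z_2^2/(z_1^2+z_2^2)$ against $\chi^2_1$; instruments must pass
$5\times10^{-8}$ upstream. Colocalization uses Wakefield approximate Bayes
factors with prior effect SD 0.15 (the quantitative-trait default) and the
standard single-causal-variant enumeration with priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$; PP4 > 0.8 claims a shared causal
variant. Record harmonization flips alleles where needed and drops records
whose effect-allele frequencies differ by more than 0.2. The HEIDI
heterogeneity test and multi-causal (SuSiE-style) colocalization are not
implemented.

## The differentiation test

If a site's NH-minus-AN methylation difference $\Delta_y$ is driven by
allele-frequency differentiation $\Delta_p$ of its meQTL variant with
effect $b$, additivity predicts $\Delta_y \approx 2\Delta_p b$.
`differentiation_test()` regresses $\Delta_y$ on $2\Delta_p b$ across DMSs
and reports both the slope test and the correlation test, since either
reading of "association" is defensible; $\Delta_p$ is oriented
target-minus-control (NH − AN), matching $\Delta_y$.

# Epigenetic clock analysis

`apply_clock()` evaluates any linear clock (JSON schema:
`{name, intercept, coef, train_means, age_transform}`); missing probes are
imputed with training means when the file provides them, else cohort means,
and fewer than 50% probe overlap is an error. `train_clock()` provides a
ridge clock (glmnet, $\alpha = 0$, penalty chosen on a held-out fold) — a
practical stand-in for BLUP-type clocks, whose shrinkage is likewise ridge
regression with the penalty tied to the signal-to-noise ratio. Published
clock files are consumed from disk; nothing is fetched from the network.

The age-acceleration residual (AAR) is predicted minus chronological age.
Records outside $[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 + 1.5\,\mathrm{IQR}]$ are
flagged and excluded; quartiles use the linear-interpolation definition and
are computed within group, and outlier removal precedes all tests (both
points are ambiguous in common practice; these choices are fixed and
documented). The omnibus test is Kruskal–Wallis. For pairwise group
differences the *unpaired* Wilcoxon rank-sum test is used: a signed-rank
(paired) test is sometimes named in this context, but the three groups are
independent samples for which no pairing exists, so the rank-sum test is
the defensible reading. Accuracy is reported as the squared Pearson
correlation between predicted and chronological age (so a sign-flipped
predictor scores 1); the $1-\mathrm{SSE}/\mathrm{SST}$ definition is
available but not the default. Phenotype-category association RINT-
transforms each phenotype within group and F-tests
$\mathrm{AAR} \sim \mathrm{age} + \mathrm{age}^2 + \text{category}$ against
the covariate-only model, at a Bonferroni level of $0.05/8$ for the eight
questionnaire/blood categories.

# The synthetic cohort

`simulate_cohort()` generates data with exactly the structure the analyses
assume, plus a truth table for recovery tests.

* **Genotypes.** Ancestral (Han) frequencies are uniform on `maf_range`;
  the Tibetan frequency comes from a Balding–Nichols beta distribution.
  Because only one lineage drifts while AN and NL keep the ancestral
  frequency, a drift parameter $c$ yields a realized pairwise Hudson Fst of
  $c/2$; the generator therefore uses $c = 2F$ so that the design parameter
  `fst` *is* the NH-vs-Han Fst (hence $F \in [0, 0.5)$). Dosages are
  Binomial(2, group frequency); variants drifting below MAF 0.01 are
  resampled.
* **Methylation.** Beta values are generated on the logit scale and
  squashed: latent = logit(baseline) + cis-meQTL dosage effect + group
  shift + age slope + batch offset + cell-fraction term + Gaussian noise.
  This keeps values in (0, 1) and makes linear-model effects approximately
  linear near 0.5. Group shifts are calibrated so the noiseless beta-scale
  difference equals `dms_effect_size` exactly; STA shifts apply to AN,
  LTA shifts to NH, with sign fractions defaulting to the observed
  asymmetry (0.2 / 0.8 hypermethylated). Each meQTL probe gets one causal
  variant within 1 Mb (multi-causal architecture is out of scope). Baselines
  default to a bimodal, array-like mixture; `baseline_range` switches to
  uniform mid-range baselines where near-linearity matters.
* **Defaults.** Group sizes default to the post-QC cohort (687/299/462).
  Effect-size distributions for real DMSs are unknown; the simulator's
  magnitudes (`dms_effect_size = 0.05`, `meqtl_effect_sd = 0.5` latent,
  age slopes ~0.02/yr latent, `noise_sd = 0.3`) are free parameters chosen
  as plausible for array data, not estimates.
* **What it does not emulate.** No array-intensity (IDAT) level simulation,
  no probe cross-reactivity, no genomic correlation structure between
  probes beyond shared covariates (so clumping behavior on real co-methylated
  regions is only approximated), no missingness beyond optional masking,
  and LD between variants is absent (each variant is drawn independently).
  Passing recovery tests therefore demonstrates correctness of the
  estimators under the generative model, not robustness to every property
  of real arrays.
* **Reproducibility.** One master seed expands to per-stage child seeds via
  a documented counter scheme; regeneration is bit-identical.

# Numerical choices and problem sizes

* Beta(a, b) MLE: Newton on the digamma score equations from a
  method-of-moments start, damped to keep shapes positive; tolerance
  $10^{-10}$ relative; explicit fallback to method-of-moments with a
  warning on failure.
* EM: parameter-change tolerance $10^{-5}$ (scaled by the MAD), up to
  10000 iterations, 5 restarts, ties in null-component selection broken by
  smallest |mean|.
* Degenerate inputs: zero-variance probes get `se = NA` and leave the
  multiple-testing count (logged); constant dosages, constant phenotypes,
  monomorphic regions, and empty groups are errors; lead ties break by
  |distance| then lexicographic variant id, so outputs are order-stable.
* The test and acceptance simulations use desk-scale sizes chosen to make
  each check sharp but cheap: 10,000 probes x 600 samples x 20 seeds for
  null calibration of the scan; 50,000 statistics for empirical-null
  recovery; 500 null probes x 1000 permutations for meQTL calibration;
  1000 pairs x 100 replicates for r~b~; 100 seeds for coloc/clock rates;
  500 probes at full cohort size for the differentiation slope.

# Known limitations

Single-variant association only (no conditional/joint meQTL modeling, no
group-by-genotype interactions); no mixed models or surrogate-variable
adjustment; no M-value analysis; enrichment does not implement gene-set
(GO/KEGG) testing; colocalization assumes a single causal variant per
region; the clock module does not construct composite biomarker ages. The
EWAS-catalog overlap consumes a frozen probe-to-trait file; no live
database is queried.
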