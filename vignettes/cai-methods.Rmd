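---
title: "The cortical asymmetry index: model, inference pipeline, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cortical asymmetry index: model, inference pipeline, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortasym)
```

## The measure

Alzheimer's disease thins the cortex, and the thinning is not perfectly
symmetric between hemispheres. The cortical asymmetry index (CAI) summarises
that asymmetry in a single scalar per scan. Each hemisphere is represented by
its 34 Desikan–Killiany regional mean thicknesses (mm); each set of 34 values
is turned into a probability distribution over a common thickness support,
and the CAI is the Jensen–Shannon *distance* between the two distributions:

$$\mathrm{CAI} = \sqrt{H(m) - \tfrac{1}{2}\left[H(p_L) + H(p_R)\right]},
\qquad m = \tfrac{1}{2}(p_L + p_R),$$

with $H$ the Shannon entropy in bits. With base-2 logarithms the squared
quantity (the Jensen–Shannon divergence) lies in $[0, 1]$, and the square
root is a true metric on distributions. CAI is therefore dimensionless,
bounded in $[0, 1]$, zero exactly when the hemispheric distributions
coincide, symmetric under hemisphere swap, and — because distributions
discard region labels — invariant to any joint permutation of the regions.

### Density estimation choices

The definition leaves the density estimator open, so the package makes the
estimator an explicit configuration (`cai_config()`) rather than a hidden
constant:

* **Histogram (default).** 16 equal-width bins over the participant's pooled
  left+right thickness range, padded by half a bin width on each side, with a
  smoothing mass of $\varepsilon = 10^{-6}$ added to every bin before
  renormalisation. A histogram with explicit smoothing is deterministic,
  auditable, and keeps the divergence finite when a bin is empty on one side
  only. 16 bins for 34 observations keeps 2 observations per bin on
  average — enough resolution to detect sub-bin-width shifts without
  degenerating into a per-value point mass.
* **Gaussian KDE (alternative).** A Gaussian kernel density (Silverman
  bandwidth) evaluated on the same grid and renormalised, available for
  sensitivity analysis via `cai_config(estimator = "gaussian_kde")`. If a
  reference implementation with a different estimator must be matched later,
  only the config changes, not the API.
* **Support policy.** The default pooled per-participant range makes CAI a
  purely within-individual measure, unaffected by cohort-level scaling or
  scanner offsets that move both hemispheres together. A fixed support
  (`support_policy = "fixed_range"`) is available for cross-cohort
  standardisation studies.
* **Unweighted regions.** The 34 regional means enter with equal weight; no
  surface-area weighting is applied, matching the representation the index
  is defined on (34 mean values per hemisphere).

Degenerate inputs: if all 68 values are identical the pooled range is empty;
a symmetric ±0.5 mm support is substituted, and the CAI is 0 as required.
Tiny negative divergences from floating-point cancellation are clamped to 0
before the square root.

## Study population structure and EYO

The pipeline targets autosomal dominant Alzheimer's disease (ADAD) cohorts.
Participants are controls (CTR, non-carrier family members, CDR 0),
asymptomatic mutation carriers (AMC, CDR 0), and symptomatic carriers (SMC,
CDR ≥ 0.5), with SMC subdivided into SMC-MCI (CDR = 0.5) and SMC-AD
(CDR ≥ 1). Because onset age is approximately heritable within families, the
estimated years to onset — EYO, the participant's age minus their affected
parent's symptom-onset age (`compute_eyo()`) — serves as the disease clock:
negative values are years before expected onset. EYO, not calendar time, is
the longitudinal axis throughout.

## The synthetic cohort generator

Participant-level data from such cohorts are not public, so the package
ships a generator (`generate_cohort()`) whose defaults *are* the study
conditions every test and the acceptance script run under. It emulates two
cohort templates with the published group sizes and group-wise EYO
distributions:

* `barcelona_like`: 19 CTR / 22 AMC / 19 SMC, cross-sectional, EYO means
  (SD) −6.4 (7.9), −9.4 (10.7), 2.4 (8.1);
* `dian_like`: 215 CTR / 234 AMC / 115 SMC (73 MCI, 42 AD), longitudinal
  with up to 7 visits, EYO means (SD) −10.4 (11.8), −14.1 (8.6), 0.5 (8.0).

Within SMC, the MCI/AD subgroup EYO means are set to −1.5/+4.0 years
(`dian_like`; 0/+5 for `barcelona_like`), chosen to average to the published
whole-SMC mean while ordering MCI before AD on the disease clock. Sampling
EYO per group from these Normals and deriving age as parental onset age
(Normal, mean 46, SD 5) plus EYO reproduces the age/EYO/group confounding
that makes covariate-adjusted inference meaningful rather than trivial.

The disease signal flows through a latent logistic burden
$b(\mathrm{EYO}) = 1/(1 + e^{-(\mathrm{EYO} - \mu)/s})$ with midpoint
$\mu = -5$ years and scale $s = 3$ years: atrophy accelerates in the years
immediately before expected onset and saturates after it. Per participant,
each region draws a baseline thickness $\sim N(2.5, 0.25^2)$ mm shared by
both hemispheres; carriers lose $0.5 \cdot b$ mm bilaterally, and the left
hemisphere's loss is inflated by the factor $(1 + \delta \cdot b)$. The
left-lateralised direction follows the prior cortical-thinning literature;
its magnitude $\delta$ has no published effect size, so the default
($\delta = 0.19$) was calibrated once so that the baseline `dian_like`
SMC-vs-CTR CAI gap is ≈ 0.5 pooled SD — a deliberately moderate effect for
power evaluation. Measurement noise is i.i.d. Gaussian (SD 0.05 mm) per
region, hemisphere and visit.

Biomarkers derive from the same burden: NfL multiplicatively
($\mathrm{baseline} \times \mathrm{fold}^{b} \times e^{\eta}$, lognormal
noise — strictly positive and right-skewed, as observed; CSF baseline
260 pg/ml with fold 4, plasma baseline 6 pg/ml with fold 3), MMSE linearly
(30 − 10·b, SD 1.2, truncated to [0, 30] and rounded), hippocampal volume
linearly downward. APOE genotypes are drawn at realistic frequencies
(~31% ε4 carriers) but are asymmetry-neutral by construction: the
published APOE-3/3 asymmetry finding is observational, and no mechanistic
link is assumed; a user wishing to inject one can act on
`left_thinning_excess` per stratum themselves.

Longitudinal visits advance age and EYO by exactly one year per visit (the
default interval); per-participant visit counts are uniform on 1..7.
Dropout is not modelled beyond that truncation.

What the generator does **not** emulate: spatially correlated regional
atrophy patterns, scanner/site effects, visit-to-visit measurement
correlation beyond the shared participant baseline, practice effects on
MMSE, or APOE effects on asymmetry. Passing tests therefore demonstrate the
pipeline's statistical behaviour under a clean, known signal — not that real
cohorts will show these effect sizes.

## Cross-sectional inference

**Covariate-adjusted permutation test.** Group differences in CAI are
tested while adjusting for age, sex and EYO (and CDR in APOE-stratified
analyses). Because "a permutation test with covariates" underdetermines the
scheme, the package implements Freedman–Lane residual permutation
(`adjusted_permutation_test()`): fit the covariate-only model, permute its
residuals, add them back to the covariate fit, refit the full model on each
pseudo-response, and use the partial $F$ for the group factor. Freedman–Lane
is the standard choice with good type-I control when nuisance covariates are
correlated with the factor of interest — exactly the situation the EYO/group
confounding creates. The statistic is the two-sided $F$; the p-value is
$(1 + \#\{F^* \ge F\})/(B + 1)$, so it can never fall below $1/(B+1)$.
Defaults: $B = 9999$ with the seed recorded in every result. Covariate
columns that carry no information in the analysed subset (single-level
factors, or columns aliased with the group design, e.g. CDR inside a
stratum where it exactly separates AMC from SMC) are dropped with a
warning rather than failing the whole run.

**ANCOVA.** For the large-cohort template the group test is an OLS fit of
`cai ~ group + age + sex + eyo` with the partial $F$ for group, and pairwise
contrasts are the model's estimated marginal mean differences (emmeans) with
Benjamini–Hochberg adjustment applied to the pairwise family. BH is applied
per analysis question: the three pairwise group contrasts form one family,
the within-genotype APOE comparisons another.

**ROC.** `roc_auc()` computes AUC by the Mann–Whitney identity (rank-based,
ties as half-pairs). All markers are oriented so that higher is more
disease-like before comparison; hippocampal volume is negated
(`roc_battery()`), keeping AUCs comparable across CAI, NfL and volume.
Point AUCs only — no DeLong intervals, matching the reporting style the
pipeline mirrors.

**Demographics.** Group demographic tables report continuous variables as
mean (SD) with Kruskal–Wallis (small cohort) or one-way ANOVA (large
cohort), and discrete variables with Fisher's exact test. Tables with more
than 2000 total observations fall back to a seeded Monte-Carlo Fisher p.
A variable with a single distinct value gets a missing p-value with a
warning rather than a fabricated 1.0.

## Associations

`association_battery()` correlates baseline CAI with age, EYO, MMSE, and
CSF/plasma NfL — Spearman for the small cohort template (rank-robust at
n ≈ 20), Pearson for the large one — within the subgroups analysed in the
target study: mutation carriers combined, SMC, and (large template) AMC,
SMC-MCI, SMC-AD. Only visit-0 rows enter; missing biomarkers are deleted
pairwise with the remaining n recorded; subgroups below n = 3 and constant
inputs are flagged, not raised. Correlation p-values are reported
unadjusted, matching the presentation they mirror (a BH option exists via
`bh_adjust()`). Age stays in the battery although no age correlation is
expected — the null is part of the validation surface. One quirk inherited
from the source material: the CSF-NfL correlation there is quoted at
"*P* < 0.5", presumed a typo for < 0.05; the package simply reports computed
p-values.

## Longitudinal trajectories

`fit_trajectory_model()` fits, by penalized least squares (mgcv, GCV-chosen
smoothing),

$$\mathrm{CAI} \sim s(\mathrm{EYO}) + \mathrm{group} +
\mathrm{group{:}EYO} + \mathrm{age} + \mathrm{sex},$$

where $s(\cdot)$ is a cubic B-spline (10 basis functions, second-order
difference penalty) shared by all groups, and the group×EYO interaction is
kept *linear* so each non-reference group yields a single slope-difference
coefficient whose $t$-statistic is the headline number — the form in which
such interactions are conventionally reported. Design details worth making
explicit:

* The interaction columns are built relative to the reference group (CTR),
  so they stay identifiable next to the smooth's unpenalized linear
  component; a full set of per-group slopes would be exactly collinear with
  it.
* Whether the EYO trend should be a smooth at all is ambiguous in a
  "fixed effects within a GAM" specification, so both modes exist:
  `smooth_eyo = FALSE` drops the spline for a purely parametric fit. On
  noiseless data both recover an injected slope difference to machine
  precision.
* **No within-participant random effects.** The model statement it mirrors
  lists none, so repeated measures are treated as independent. This is a
  real limitation: standard errors are valid only to the extent that
  within-participant correlation is negligible. Under the package's own
  generator that correlation is weak (hemisphere-shared baselines cancel in
  the left/right comparison, leaving mostly visit-level noise), and the
  empirical null rejection rate of the interaction test stays near 5%; on
  real data with strong participant-level asymmetry traits the test could
  be anticonservative.
* Grouping variants mirror the three reported analyses: CTR vs carriers,
  CTR/AMC/SMC, CTR/AMC/SMC-MCI/SMC-AD.

`predict_trajectories()` evaluates group curves over an EYO grid at
reference covariates (mean age, sex-balanced average) with pointwise
standard errors from the coefficient covariance. Prediction outside the
fitted EYO range errors unless explicitly allowed, in which case the smooth
is frozen at its boundary value and only the parametric terms continue
linearly — extrapolation never invents spline behaviour beyond the data.

Estimator calibration (type-I error, noiseless recovery) is checked against
`simulate_trajectory_data()`, a direct simulator of the model's own
assumption (i.i.d. Gaussian noise around group-linear EYO trends); power is
checked against full `generate_cohort()` cohorts, where the CAI noise
distribution is whatever the thickness-level process produces.

## Orchestration and reproducibility

`run_pipeline(run_config(...))` executes ingest → CAI → cross-sectional →
associations → APOE-stratified → longitudinal as one run, writing a results
bundle (analysis table, demographics, group tests, ROC, correlations, APOE
tests, GAM interactions, trajectory grids) plus `manifest.json` recording
package version, a config hash, all seeds and per-stage row counts; any
stage failure aborts with the stage name. All randomness flows from named
seeds, and numeric CSV output is written at full precision through a fixed
formatter, so a rerun with the same config is byte-identical. The numbered
scripts under `analysis/` drive the same exported functions; there is no
separate command-line layer.

## Problem sizes used in validation

The test-suite and acceptance-script replicate counts are fixed study
choices: 1000 random distribution pairs for the Jensen–Shannon oracle; 100
simulated participants per thinning offset; 500 null datasets (n = 60, 999
permutations) for permutation-test calibration; 100 `dian_like` replicates
for power, AUC and association-sign recovery; 100 stochastic GAM fits for
interaction power and 1000 for its null calibration. At these sizes a 5%
null rate is estimated with a ≤1% standard error and power/sign rates with
≤5% standard error, which is the resolution the pass criteria need.

## Known limitations

* CAI is a single whole-brain scalar; it does not localise asymmetry to
  regions, by design.
* The histogram estimator's noise floor (CAI ≈ 0.35 for identical-mean
  hemispheres at measurement noise SD 0.05 mm) means raw CAI values are not
  comparable across different estimator settings; comparisons must hold the
  config fixed.
* Repeated measures are modelled without random effects (above).
* The generator's effect sizes are calibrated study conditions, not
  estimates from data; nothing here validates the biological magnitude of
  asymmetry in real ADAD cohorts.
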