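# cortasym

Cortical thinning in Alzheimer's disease is not perfectly symmetric between
hemispheres, and the asymmetry appears to grow with disease stage. The
**cortical asymmetry index (CAI)** summarises that asymmetry in one scalar
per scan: each hemisphere's 34 Desikan–Killiany regional mean thicknesses
are turned into a probability distribution over a common thickness support,
and the CAI is the Jensen–Shannon distance between the two distributions,

CAI = sqrt( H(m) − [H(p_L) + H(p_R)] / 2 ),  m = (p_L + p_R) / 2,

with H the Shannon entropy in bits — dimensionless, bounded in [0, 1],
zero for identical hemispheres, higher meaning a more asymmetric brain.

`cortasym` implements the index and the full inference pipeline used to
study it in autosomal dominant Alzheimer's disease (ADAD) cohorts, for
neuroimaging statisticians working with FreeSurfer regional thickness
exports:

* **Ingest** — `aparcstats2table`-style wide tables or long CSVs
  (`read_thickness()`), participant metadata with CDR/group consistency
  checks and derived fields (`read_metadata()`), EYO computation
  (`compute_eyo()`).
* **CAI** — `compute_cai()` / `compute_cai_table()` with a configurable
  density estimator (`cai_config()`: 16-bin smoothed histogram by default,
  Gaussian KDE as an alternative).
* **Cross-sectional inference** — Freedman–Lane covariate-adjusted
  permutation tests (`adjusted_permutation_test()`), ANCOVA with
  BH-corrected pairwise contrasts (`ancova_group_test()`), APOE-stratified
  comparisons (`apoe_stratified_tests()`), Mann–Whitney ROC AUCs
  (`roc_auc()`, `roc_battery()`), demographics tables
  (`demographics_table()`).
* **Associations** — Spearman/Pearson batteries of CAI against age, EYO,
  MMSE and NfL by clinical subgroup (`association_battery()`).
* **Longitudinal trajectories** — penalized B-spline GAM of CAI on EYO with
  linear group×EYO interactions (`fit_trajectory_model()`,
  `predict_trajectories()`).
* **Synthetic cohorts** — `generate_cohort()` draws ADAD-like cohorts
  (group sizes, EYO distributions, NfL/MMSE links, longitudinal visits)
  with a controllable left-lateralised thinning excess, so the entire
  pipeline runs and is testable without participant-level data.
* **Orchestration** — `run_pipeline(run_config(...))` executes everything
  as one seeded, byte-reproducible run with a JSON manifest.

See the methods vignette (`vignettes/cai-methods.Rmd`) for the model,
design decisions and limitations.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
cohorts: `01_simulate_cohorts.R` writes two cohorts' raw tables,
`02_compute_cai.R` ingests them and appends CAI, `03`–`05` run the
cross-sectional, association and longitudinal analyses, writing tables
under `results/`. Running them in order prints, among other things:

```
dian_like       564 participants (215 CTR / 234 AMC / 115 SMC), 2269 visits total
dian_like       mean baseline CAI: CTR 0.355 | AMC 0.355 | SMC 0.388
carriers vs CTR (perm, age/sex/EYO adjusted): F = 3.97, p = 0.0446
three-group ANCOVA: F = 4.30, p = 0.01396
  group_a group_b estimate   p_raw p_adjusted
1     AMC     CTR  0.00565 0.42491     0.4249
2     AMC     SMC -0.02023 0.03220     0.0483
3     CTR     SMC -0.02588 0.00351     0.0105
CAI AUCs: SMC|CTR 0.63, SMC|AMC 0.63, AMC|CTR 0.50
```

Read: in the large synthetic cohort, symptomatic carriers are measurably
more asymmetric than controls (BH-adjusted p = 0.0105) while asymptomatic
carriers are not distinguishable from controls at baseline — the covariate
structure (age/EYO/group confounding) is realistic enough that adjustment
matters. The association battery finds CAI rising with plasma NfL
(r = 0.29) and EYO (r = 0.33) and falling with MMSE (r = −0.35) in
carriers, and the GAM finds a positive SMC×EYO slope difference
(t = 4.84, p < 1e-5): asymmetry grows as carriers approach and pass
expected onset. All of this is generated signal — the generator injects
burden-proportional left-lateralised thinning — so the numbers validate
the pipeline's behaviour, not any real cohort.

A minimal programmatic session:

```r
library(cortasym)
coh <- generate_cohort(synthetic_config("dian_like", seed = 11))
at  <- build_analysis_table(coh, cai_config())
base <- at[at$visit == 0, ]
carrier <- factor(ifelse(base$group == "CTR", "CTR", "carriers"))
adjusted_permutation_test(
  base$cai, carrier,
  base[, c("age_years", "sex", "eyo_years")],
  n_permutations = 9999, seed = 1
)
```

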