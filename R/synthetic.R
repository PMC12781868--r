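#' Logistic disease-burden curve over EYO
#'
#' Maps estimated years from symptom onset to a latent disease burden in
#' (0, 1): `1 / (1 + exp(-(eyo - midpoint) / scale))`. Burden 0.5 at the
#' midpoint, approaching 0 far before onset and 1 past it; strictly
#' increasing in EYO.
#'
#' @param eyo_years EYO (years; negative before expected onset). Vectorised.
#' @param midpoint_eyo EYO at which burden reaches 0.5 (years).
#' @param scale_years Logistic scale (years, > 0); smaller is steeper.
#' @return Burden values in (0, 1).
#' @export
#' @examples
#' burden(-2, midpoint_eyo = -5, scale_years = 3) # 1 / (1 + exp(-1))
burden <- function(eyo_years, midpoint_eyo = -5, scale_years = 3) {
  if (!is_scalar_number(scale_years) || scale_years <= 0) {
    stop_domain("`scale_years` must be a positive number")
  }
  1 / (1 + exp(-(eyo_years - midpoint_eyo) / scale_years))
}

#' Configuration for the synthetic ADAD cohort generator
#'
#' Defaults emulate the structure of the two observational ADAD cohorts the
#' pipeline targets: a small single-centre cohort (`barcelona_like`,
#' cross-sectional, 19/22/19 CTR/AMC/SMC) and a large multi-centre cohort
#' (`dian_like`, longitudinal, 215/234/115 with the SMC split 73 MCI / 42 AD).
#' Group-specific EYO distributions are Normal with the published cohort
#' means/SDs, which reproduces the realistic age/EYO/group confounding that
#' makes covariate-adjusted inference meaningful.
#'
#' Thickness model, per participant: each of the 34 regional means has a
#' participant-level baseline `~ Normal(region_mean_mm, region_sd_mm)` shared
#' by both hemispheres; in mutation carriers both hemispheres are thinned by
#' `atrophy_max_mm * burden(EYO)` and the left hemisphere's thinning is
#' additionally inflated by the factor `(1 + left_thinning_excess *
#' burden(EYO))`, so asymmetry grows with disease stage; i.i.d. Gaussian
#' measurement noise is added per region, hemisphere and visit. Plasma and
#' CSF NfL follow multiplicative lognormal links (`baseline *
#' fold^burden * exp(noise)`) — strictly positive and right-skewed — and MMSE
#' declines linearly in burden with truncation to \[0, 30\].
#'
#' @param cohort_template `"dian_like"` (default) or `"barcelona_like"`.
#' @param n_per_group Named integer vector over CTR, AMC, SMC_MCI, SMC_AD.
#' @param region_mean_mm,region_sd_mm Population mean and between-region SD of
#'   baseline regional thickness (mm).
#' @param measurement_noise_sd_mm Per-measurement Gaussian noise SD (mm).
#' @param atrophy_max_mm Maximum burden-driven bilateral thinning (mm).
#' @param midpoint_eyo,scale_years Parameters of the [burden()] curve.
#' @param left_thinning_excess Non-negative dial controlling how much extra
#'   burden-proportional thinning the left hemisphere receives. The default is
#'   calibrated so the baseline `dian_like` SMC-vs-CTR CAI gap is about half a
#'   pooled SD.
#' @param nfl_csf_link,nfl_plasma_link Lists with `baseline_pg_ml`,
#'   `fold_increase_per_unit_burden`, `lognormal_noise_sd`.
#' @param mmse_link List with `max_score`, `points_lost_per_unit_burden`,
#'   `noise_sd`.
#' @param hippocampus_link List with `baseline_mm3`, `loss_mm3_per_unit_burden`,
#'   `noise_sd_mm3`.
#' @param apoe_frequencies Named probability vector over the six genotypes;
#'   asymmetry-neutral by construction (no APOE term enters the thickness
#'   model).
#' @param gene_frequencies Named probability vector over PSEN1, PSEN2, APP for
#'   carriers.
#' @param prob_female Probability a participant is female.
#' @param parent_onset_mean_years,parent_onset_sd_years Parental symptom-onset
#'   age distribution (years); participant age is `parent onset + EYO`.
#' @param n_visits Maximum visits per participant (baseline plus up to six
#'   follow-ups, so at most 7); each participant's visit count is uniform on
#'   `1..n_visits`.
#' @param visit_interval_years Years between consecutive visits.
#' @param seed Integer RNG seed; generation is fully deterministic given it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    cohort_template = c("dian_like", "barcelona_like"),
    n_per_group = NULL,
    region_mean_mm = 2.5,
    region_sd_mm = 0.25,
    measurement_noise_sd_mm = 0.05,
    atrophy_max_mm = 0.5,
    midpoint_eyo = -5,
    scale_years = 3,
    left_thinning_excess = 0.19,
    nfl_csf_link = list(baseline_pg_ml = 260, fold_increase_per_unit_burden = 4,
                        lognormal_noise_sd = 0.3),
    nfl_plasma_link = list(baseline_pg_ml = 6, fold_increase_per_unit_burden = 3,
                           lognormal_noise_sd = 0.4),
    mmse_link = list(max_score = 30, points_lost_per_unit_burden = 10,
                     noise_sd = 1.2),
    hippocampus_link = list(baseline_mm3 = 8000, loss_mm3_per_unit_burden = 2500,
                            noise_sd_mm3 = 400),
    apoe_frequencies = c("2/2" = 0.01, "2/3" = 0.08, "2/4" = 0.02,
                         "3/3" = 0.60, "3/4" = 0.25, "4/4" = 0.04),
    gene_frequencies = c(PSEN1 = 0.80, PSEN2 = 0.05, APP = 0.15),
    prob_female = 0.6,
    parent_onset_mean_years = 46,
    parent_onset_sd_years = 5,
    n_visits = NULL,
    visit_interval_years = 1,
    seed = 20260101L) {
  cohort_template <- match.arg(cohort_template)
  if (is.null(n_per_group)) {
    n_per_group <- if (cohort_template == "dian_like") {
      c(CTR = 215L, AMC = 234L, SMC_MCI = 73L, SMC_AD = 42L)
    } else {
      c(CTR = 19L, AMC = 22L, SMC_MCI = 10L, SMC_AD = 9L)
    }
  }
  if (is.null(n_visits)) {
    n_visits <- if (cohort_template == "dian_like") 7L else 1L
  }
  cfg <- list(
    cohort_template = cohort_template,
    n_per_group = n_per_group,
    region_mean_mm = region_mean_mm,
    region_sd_mm = region_sd_mm,
    measurement_noise_sd_mm = measurement_noise_sd_mm,
    atrophy_max_mm = atrophy_max_mm,
    midpoint_eyo = midpoint_eyo,
    scale_years = scale_years,
    left_thinning_excess = left_thinning_excess,
    nfl_csf_link = nfl_csf_link,
    nfl_plasma_link = nfl_plasma_link,
    mmse_link = mmse_link,
    hippocampus_link = hippocampus_link,
    apoe_frequencies = apoe_frequencies,
    gene_frequencies = gene_frequencies,
    prob_female = prob_female,
    parent_onset_mean_years = parent_onset_mean_years,
    parent_onset_sd_years = parent_onset_sd_years,
    n_visits = as.integer(n_visits),
    visit_interval_years = visit_interval_years,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  req_groups <- c("CTR", "AMC", "SMC_MCI", "SMC_AD")
  if (!all(req_groups %in% names(cfg$n_per_group)) ||
      any(cfg$n_per_group[req_groups] < 1)) {
    stop_validation("`n_per_group` must name positive counts for %s",
                    paste(req_groups, collapse = ", "))
  }
  if (abs(sum(cfg$apoe_frequencies) - 1) > 1e-8) {
    stop_validation("`apoe_frequencies` must sum to 1")
  }
  if (abs(sum(cfg$gene_frequencies) - 1) > 1e-8) {
    stop_validation("`gene_frequencies` must sum to 1")
  }
  sds <- c(cfg$region_sd_mm, cfg$measurement_noise_sd_mm,
           cfg$nfl_csf_link$lognormal_noise_sd,
           cfg$nfl_plasma_link$lognormal_noise_sd, cfg$mmse_link$noise_sd,
           cfg$hippocampus_link$noise_sd_mm3, cfg$parent_onset_sd_years)
  if (any(sds < 0)) stop_validation("all standard deviations must be >= 0")
  if (cfg$n_visits < 1L || cfg$n_visits > 7L) {
    stop_validation("`n_visits` must be between 1 (baseline only) and 7")
  }
  if (cfg$visit_interval_years <= 0) {
    stop_validation("`visit_interval_years` must be positive")
  }
  if (cfg$left_thinning_excess < 0) {
    stop_validation("`left_thinning_excess` must be non-negative")
  }
  if (cfg$scale_years <= 0) stop_validation("`scale_years` must be positive")
  invisible(cfg)
}

# Group-level EYO distributions (mean, sd) patterned on the two cohorts'
# published demographics; the SMC subgroup means are chosen to average to the
# published whole-SMC mean while ordering MCI < AD.
eyo_distributions <- list(
  barcelona_like = list(
    CTR = c(-6.4, 7.9), AMC = c(-9.4, 10.7),
    SMC_MCI = c(0.0, 8.1), SMC_AD = c(5.0, 8.1)
  ),
  dian_like = list(
    CTR = c(-10.4, 11.8), AMC = c(-14.1, 8.6),
    SMC_MCI = c(-1.5, 8.0), SMC_AD = c(4.0, 8.0)
  )
)

#' Generate a synthetic ADAD cohort
#'
#' Draws a full [cohort_table()] — participant metadata plus left/right
#' regional thickness profiles, longitudinal where configured — from a
#' [synthetic_config()]. Deterministic given the config's seed; the caller's
#' RNG state is left untouched.
#'
#' @param config A [synthetic_config()].
#' @return A [cohort_table()].
#' @export
#' @examples
#' cfg <- synthetic_config("barcelona_like", seed = 7)
#' coh <- generate_cohort(cfg)
#' table(coh$metadata$group[coh$metadata$visit == 0])
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, config)
  }
  validate_synthetic_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  groups <- c("CTR", "AMC", "SMC_MCI", "SMC_AD")
  n <- sum(cfg$n_per_group[groups])
  subgroup <- rep(groups, cfg$n_per_group[groups])
  group <- ifelse(subgroup %in% c("SMC_MCI", "SMC_AD"), "SMC", subgroup)
  id <- sprintf("%s-%04d", toupper(substr(cfg$cohort_template, 1, 3)), seq_len(n))

  eyo_pars <- eyo_distributions[[cfg$cohort_template]]
  eyo0 <- vapply(subgroup, function(g) {
    rnorm(1, eyo_pars[[g]][1], eyo_pars[[g]][2])
  }, numeric(1))
  parent_onset <- pmax(rnorm(n, cfg$parent_onset_mean_years,
                             cfg$parent_onset_sd_years), 25)
  # keep baseline ages positive even deep before onset
  eyo0 <- pmax(eyo0, 18 - parent_onset)
  age0 <- parent_onset + eyo0

  sex <- ifelse(runif(n) < cfg$prob_female, "female", "male")
  gene <- ifelse(
    group == "CTR", "none",
    sample(names(cfg$gene_frequencies), n, replace = TRUE,
           prob = cfg$gene_frequencies)
  )
  apoe <- sample(names(cfg$apoe_frequencies), n, replace = TRUE,
                 prob = cfg$apoe_frequencies)
  cdr <- ifelse(subgroup == "SMC_MCI", 0.5,
                ifelse(subgroup == "SMC_AD", sample(c(1, 2), n, TRUE, c(0.8, 0.2)), 0))

  n_visits_i <- if (cfg$n_visits == 1L) rep(1L, n) else
    sample.int(cfg$n_visits, n, replace = TRUE)

  # participant-level regional baselines, shared across hemispheres and visits
  base_thick <- matrix(
    rnorm(n * 34, cfg$region_mean_mm, cfg$region_sd_mm),
    nrow = n, ncol = 34, dimnames = list(id, dk_regions)
  )
  base_thick[base_thick < 1] <- 1  # physical floor, mm

  # expand participants to one row per visit
  pid <- rep.int(seq_len(n), n_visits_i)
  nvtot <- length(pid)
  visit <- unlist(lapply(n_visits_i, function(k) seq_len(k) - 1L), use.names = FALSE)
  eyo_v <- eyo0[pid] + visit * cfg$visit_interval_years
  age_v <- age0[pid] + visit * cfg$visit_interval_years
  carrier <- group[pid] != "CTR"
  b_v <- ifelse(carrier, burden(eyo_v, cfg$midpoint_eyo, cfg$scale_years), 0)

  thin_right <- cfg$atrophy_max_mm * b_v
  thin_left <- thin_right * (1 + cfg$left_thinning_excess * b_v)
  noise <- matrix(rnorm(nvtot * 68, 0, cfg$measurement_noise_sd_mm), nrow = nvtot)
  base_v <- base_thick[pid, , drop = FALSE]
  left <- pmax(base_v - thin_left + noise[, 1:34, drop = FALSE], 0.2)
  right <- pmax(base_v - thin_right + noise[, 35:68, drop = FALSE], 0.2)

  lk_c <- cfg$nfl_csf_link
  lk_p <- cfg$nfl_plasma_link
  csf <- lk_c$baseline_pg_ml * lk_c$fold_increase_per_unit_burden^b_v *
    rlnorm(nvtot, 0, lk_c$lognormal_noise_sd)
  plasma <- lk_p$baseline_pg_ml * lk_p$fold_increase_per_unit_burden^b_v *
    rlnorm(nvtot, 0, lk_p$lognormal_noise_sd)
  mmse <- round(pmin(pmax(
    cfg$mmse_link$max_score - cfg$mmse_link$points_lost_per_unit_burden * b_v +
      rnorm(nvtot, 0, cfg$mmse_link$noise_sd), 0), cfg$mmse_link$max_score))
  hip <- pmax(cfg$hippocampus_link$baseline_mm3 -
                cfg$hippocampus_link$loss_mm3_per_unit_burden * b_v +
                rnorm(nvtot, 0, cfg$hippocampus_link$noise_sd_mm3), 1000)

  group_v <- group[pid]
  subgroup_v <- ifelse(group_v == "SMC", subgroup[pid], "none")
  metadata <- tibble::tibble(
    participant_id = id[pid],
    cohort = cfg$cohort_template,
    group = group_v,
    smc_subgroup = subgroup_v,
    mutation_gene = gene[pid],
    apoe_genotype = apoe[pid],
    apoe_e4_carrier = grepl("4", apoe[pid]),
    sex = sex[pid],
    age_years = age_v,
    parent_onset_age_years = parent_onset[pid],
    eyo_years = eyo_v,
    cdr = cdr[pid],
    mmse = mmse,
    csf_nfl_pg_ml = csf,
    plasma_nfl_pg_ml = plasma,
    hippocampal_volume_mm3 = hip,
    visit = visit
  )
  thickness <- tibble::tibble(
    participant_id = rep(id[pid], each = 68L),
    visit = rep(visit, each = 68L),
    hemisphere = rep(rep(c("left", "right"), each = 34L), nvtot),
    region = rep(dk_regions, 2L * nvtot),
    # row i of cbind(left, right) flattens to that visit's 68 values
    thickness_mm = as.numeric(t(cbind(left, right)))
  )
  cohort_table(metadata, thickness)
}
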