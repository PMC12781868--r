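#' Fit the longitudinal CAI trajectory model
#'
#' Penalized-spline regression of CAI on EYO with parametric group, linear
#' group-by-EYO interaction, age and sex terms:
#' `cai ~ s(eyo, bs = "ps") + group + group:eyo + age + sex`, fitted by
#' [mgcv::gam()] with the smoothing parameter chosen by generalized cross
#' validation. The common smooth captures the shared nonlinear EYO trend; the
#' interaction is kept linear so each non-reference group contributes a
#' single slope-difference coefficient whose t-test is the headline
#' statistic. Group-specific interaction columns are built relative to the
#' reference group (CTR), so they are identifiable next to the smooth's
#' unpenalized linear component. Repeated measures are treated as
#' independent: the model has no within-participant random effects.
#'
#' @param data Analysis table (all visits): needs `cai`, `eyo_years`,
#'   `age_years`, `sex`, `group`, `smc_subgroup`, `participant_id`.
#' @param grouping `"carriers_vs_ctr"` (CTR vs all carriers),
#'   `"three_group"` (CTR/AMC/SMC) or `"four_group"`
#'   (CTR/AMC/SMC_MCI/SMC_AD). CTR is always the reference level.
#' @param n_basis Number of B-spline basis functions for the EYO smooth.
#' @param penalty_order Difference-penalty order.
#' @param smooth_eyo If `FALSE`, drop the smooth and fit the purely
#'   parametric model (common linear EYO trend instead of `s(EYO)`).
#' @return A list of class `gam_fit`: the mgcv `model`, `grouping`,
#'   `interaction_tests` (tibble: group, estimate, se, t, p),
#'   `parametric_terms`, `eyo_range`, `n_observations`, `n_participants`.
#' @export
fit_trajectory_model <- function(data,
                                 grouping = c("three_group", "carriers_vs_ctr",
                                              "four_group"),
                                 n_basis = 10L, penalty_order = 2L,
                                 smooth_eyo = TRUE) {
  grouping <- match.arg(grouping)
  d <- data[is.finite(data$cai) & is.finite(data$eyo_years) &
              is.finite(data$age_years) & !is.na(data$sex), ]
  d <- tibble::as_tibble(d)
  d$traj_group <- trajectory_grouping(d, grouping)
  d <- d[order(d$participant_id, d$visit), ]

  levs <- levels(d$traj_group)
  present <- levs[levs %in% unique(as.character(d$traj_group))]
  if (length(present) < 2L) stop_contract("need at least two groups present")
  d$traj_group <- factor(as.character(d$traj_group), levels = present)
  for (g in present) {
    spread <- unique(d$eyo_years[d$traj_group == g])
    if (length(spread) < 3L) {
      stop_validation(
        "group %s has fewer than 3 distinct EYO values; no longitudinal spread", g
      )
    }
  }
  d$sex <- factor(d$sex, levels = c("female", "male"))

  # explicit reference-coded interaction columns: slope offsets vs CTR
  inter_cols <- paste0("eyo_x_", make.names(present[-1]))
  for (k in seq_along(inter_cols)) {
    d[[inter_cols[k]]] <- as.numeric(d$traj_group == present[-1][k]) * d$eyo_years
  }

  rhs <- c(
    if (smooth_eyo) {
      sprintf("s(eyo_years, bs = 'ps', k = %d, m = c(2, %d))",
              as.integer(n_basis), as.integer(penalty_order))
    } else {
      "eyo_years"
    },
    "traj_group", inter_cols, "age_years", "sex"
  )
  form <- as.formula(paste("cai ~", paste(rhs, collapse = " + ")))
  model <- mgcv::gam(form, data = d, method = "GCV.Cp")

  pt <- summary(model)$p.table
  it_rows <- match(inter_cols, rownames(pt))
  interaction_tests <- tibble::tibble(
    group = present[-1],
    estimate = pt[it_rows, "Estimate"],
    se = pt[it_rows, "Std. Error"],
    t = pt[it_rows, "t value"],
    p = pt[it_rows, "Pr(>|t|)"]
  )
  structure(
    list(
      model = model,
      grouping = grouping,
      groups = present,
      interaction_tests = interaction_tests,
      parametric_terms = pt,
      smooth_eyo = smooth_eyo,
      eyo_range = range(d$eyo_years),
      reference_age = mean(d$age_years),
      n_observations = nrow(d),
      n_participants = length(unique(d$participant_id)),
      gcv = model$gcv.ubre
    ),
    class = "gam_fit"
  )
}

trajectory_grouping <- function(d, grouping) {
  switch(
    grouping,
    carriers_vs_ctr = factor(
      ifelse(d$group == "CTR", "CTR", "carriers"),
      levels = c("CTR", "carriers")
    ),
    three_group = factor(d$group, levels = c("CTR", "AMC", "SMC")),
    four_group = factor(
      ifelse(d$group == "SMC", d$smc_subgroup, d$group),
      levels = c("CTR", "AMC", "SMC_MCI", "SMC_AD")
    )
  )
}

#' @export
print.gam_fit <- function(x, ...) {
  cat(sprintf(
    "<gam_fit> %s: %d observations, %d participants, EYO range [%.1f, %.1f]\n",
    x$grouping, x$n_observations, x$n_participants,
    x$eyo_range[1], x$eyo_range[2]
  ))
  print(x$interaction_tests)
  invisible(x)
}

#' Predicted group trajectories over an EYO grid
#'
#' Model predictions at reference covariates: mean age of the fitted data and
#' a balanced sex mix (the average of the female and male predictions), with
#' pointwise standard errors from the fitted covariance.
#'
#' @param fit A [fit_trajectory_model()] result.
#' @param eyo_grid Numeric grid of EYO values. Must lie within the fitted
#'   range unless `allow_extrapolation = TRUE`.
#' @param allow_extrapolation If `TRUE`, grid points beyond the fitted EYO
#'   range are predicted by freezing the smooth at its boundary value and
#'   continuing only the parametric (linear) terms.
#' @return Tibble: group, eyo, fit, se.
#' @export
predict_trajectories <- function(fit, eyo_grid, allow_extrapolation = FALSE) {
  stopifnot(inherits(fit, "gam_fit"))
  rng <- fit$eyo_range
  outside <- eyo_grid < rng[1] | eyo_grid > rng[2]
  if (any(outside) && !allow_extrapolation) {
    stop_validation(
      "EYO grid extends beyond the fitted range [%.2f, %.2f]; set allow_extrapolation = TRUE for parametric-only continuation",
      rng[1], rng[2]
    )
  }
  groups <- fit$groups
  out <- list()
  beta <- coef(fit$model)
  V <- fit$model$Vp
  for (g in groups) {
    X <- lapply(c("female", "male"), function(sx) {
      nd <- trajectory_newdata(fit, eyo_grid, g, sx)
      Xs <- predict(fit$model, newdata = nd, type = "lpmatrix")
      if (any(outside)) {
        # freeze smooth columns at the boundary for extrapolated points
        nd_cl <- nd
        nd_cl$eyo_years <- pmin(pmax(eyo_grid, rng[1]), rng[2])
        # interaction columns keep their true (unclamped) eyo
        Xc <- predict(fit$model, newdata = nd_cl, type = "lpmatrix")
        sm_cols <- smooth_col_idx(fit$model)
        Xs[outside, sm_cols] <- Xc[outside, sm_cols]
      }
      Xs
    })
    Xavg <- (X[[1]] + X[[2]]) / 2
    pred <- as.numeric(Xavg %*% beta)
    se <- sqrt(pmax(rowSums((Xavg %*% V) * Xavg), 0))
    out[[g]] <- tibble::tibble(group = g, eyo = eyo_grid, fit = pred, se = se)
  }
  dplyr::bind_rows(out)
}

trajectory_newdata <- function(fit, eyo_grid, g, sx) {
  nd <- tibble::tibble(
    eyo_years = eyo_grid,
    traj_group = factor(g, levels = fit$groups),
    age_years = fit$reference_age,
    sex = factor(sx, levels = c("female", "male"))
  )
  for (gg in fit$groups[-1]) {
    nd[[paste0("eyo_x_", make.names(gg))]] <- as.numeric(g == gg) * eyo_grid
  }
  nd
}

smooth_col_idx <- function(model) {
  if (length(model$smooth) == 0) return(integer(0))
  unlist(lapply(model$smooth, function(s) s$first.para:s$last.para))
}

#' Simulate idealized CAI trajectory data
#'
#' Direct simulator of longitudinal CAI observations under the trajectory
#' model's own error assumption (i.i.d. Gaussian noise around group-level
#' linear EYO trends) — used for estimator calibration checks, where the
#' question is the model's behaviour given data that satisfy its
#' assumptions, not the full thickness-level generative process (for that,
#' see [generate_cohort()]).
#'
#' @param n_per_group Participants per group.
#' @param slopes Named vector of CAI-per-EYO-year slopes, one per group; the
#'   names define the groups (first = CTR reference).
#' @param intercept CAI level at EYO 0.
#' @param noise_sd SD of the i.i.d. observation noise (CAI units).
#' @param n_visits Visits per participant; EYO advances by 1 year per visit.
#' @param eyo_baseline_range Uniform range for baseline EYO.
#' @param seed Integer seed.
#' @return Tibble shaped like an analysis table (columns `participant_id`,
#'   `visit`, `group`, `smc_subgroup`, `sex`, `age_years`, `eyo_years`,
#'   `cai`).
#' @export
simulate_trajectory_data <- function(n_per_group = 40L,
                                     slopes = c(CTR = 0, SMC = 0.01),
                                     intercept = 0.2,
                                     noise_sd = 0.03,
                                     n_visits = 4L,
                                     eyo_baseline_range = c(-15, 5),
                                     seed = 1L) {
  groups <- names(slopes)
  with_seed(seed, {
    rows <- list()
    k <- 0L
    for (g in groups) {
      for (i in seq_len(n_per_group)) {
        k <- k + 1L
        eyo0 <- runif(1, eyo_baseline_range[1], eyo_baseline_range[2])
        visits <- seq_len(n_visits) - 1L
        eyo <- eyo0 + visits
        # parental onset age varies between families, so age is correlated
        # with, but not collinear to, EYO
        age0 <- runif(1, 38, 54) + eyo0
        cai <- intercept + slopes[[g]] * eyo +
          rnorm(length(visits), 0, noise_sd)
        rows[[k]] <- tibble::tibble(
          participant_id = sprintf("%s-%03d", g, i),
          visit = visits,
          group = g,
          smc_subgroup = if (g %in% c("SMC_MCI", "SMC_AD")) g else "none",
          sex = if (i %% 2 == 0) "female" else "male",
          age_years = age0 + visits,
          eyo_years = eyo,
          cai = cai
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}
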