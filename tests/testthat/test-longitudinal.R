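test_that("the interaction coefficient is recovered exactly on noiseless data", {
  d <- simulate_trajectory_data(n_per_group = 25,
                                slopes = c(CTR = 0, SMC = 0.01),
                                noise_sd = 0, seed = 3)
  fit <- fit_trajectory_model(d, "three_group")
  smc <- fit$interaction_tests[fit$interaction_tests$group == "SMC", ]
  expect_equal(smc$estimate, 0.01, tolerance = 1e-6)
  # interpolation of an exact fit
  pred <- predict_trajectories(fit, seq(-10, 2, length.out = 9))
  smc_line <- pred[pred$group == "SMC", ]
  expect_equal(smc_line$fit, 0.2 + 0.01 * smc_line$eyo, tolerance = 1e-6)
  ctr_line <- pred[pred$group == "CTR", ]
  expect_equal(diff(range(diff(ctr_line$fit))), 0, tolerance = 1e-6)
})

test_that("the parametric (no-smooth) variant recovers the same interaction", {
  d <- simulate_trajectory_data(n_per_group = 25,
                                slopes = c(CTR = 0.003, SMC = 0.013),
                                noise_sd = 0, seed = 4)
  fit <- fit_trajectory_model(d, "three_group", smooth_eyo = FALSE)
  expect_equal(fit$interaction_tests$estimate[1], 0.01, tolerance = 1e-6)
})

test_that("the fit is invariant to row order", {
  d <- simulate_trajectory_data(n_per_group = 15, noise_sd = 0.03, seed = 5)
  f1 <- fit_trajectory_model(d, "three_group")
  set.seed(6)
  f2 <- fit_trajectory_model(d[sample.int(nrow(d)), ], "three_group")
  expect_equal(f1$interaction_tests$estimate, f2$interaction_tests$estimate,
               tolerance = 1e-10)
  expect_equal(f1$interaction_tests$t, f2$interaction_tests$t, tolerance = 1e-10)
})

test_that("groups without longitudinal spread are rejected with a clear error", {
  d <- simulate_trajectory_data(n_per_group = 10, noise_sd = 0.02, seed = 7)
  d$eyo_years[d$group == "SMC"] <- 0
  expect_error(fit_trajectory_model(d, "three_group"), "EYO",
               class = "cortasym_validation_error")
})

test_that("extrapolation requires the explicit flag and then continues the parametric part linearly", {
  d <- simulate_trajectory_data(n_per_group = 25,
                                slopes = c(CTR = 0, SMC = 0.01),
                                noise_sd = 0, seed = 8)
  fit <- fit_trajectory_model(d, "three_group")
  hi <- fit$eyo_range[2]
  expect_error(predict_trajectories(fit, hi + c(1, 2)),
               class = "cortasym_validation_error")
  ext <- predict_trajectories(fit, hi + c(1, 2), allow_extrapolation = TRUE)
  smc <- ext[ext$group == "SMC", ]
  # smooth frozen at the boundary, interaction slope continues: the SMC curve
  # keeps its 0.01/year slope beyond the fitted range
  expect_equal(diff(smc$fit), 0.01, tolerance = 1e-6)
  ctr <- ext[ext$group == "CTR", ]
  expect_equal(diff(ctr$fit), 0, tolerance = 1e-6)
})

test_that("trajectory groupings mirror the three reported analyses", {
  at <- build_analysis_table(generate_cohort(small_synth(seed = 12)))
  f2 <- fit_trajectory_model(at, "carriers_vs_ctr")
  expect_identical(f2$groups, c("CTR", "carriers"))
  f3 <- fit_trajectory_model(at, "three_group")
  expect_identical(f3$groups, c("CTR", "AMC", "SMC"))
  f4 <- fit_trajectory_model(at, "four_group")
  expect_identical(f4$groups, c("CTR", "AMC", "SMC_MCI", "SMC_AD"))
  expect_equal(nrow(f4$interaction_tests), 3)
})

test_that("fitted end-of-range CAI preserves the burden ordering of the generator", {
  cfg <- synthetic_config(
    "dian_like",
    n_per_group = c(CTR = 80L, AMC = 80L, SMC_MCI = 50L, SMC_AD = 40L),
    seed = 13
  )
  at <- build_analysis_table(generate_cohort(cfg))
  fit <- fit_trajectory_model(at, "four_group")
  hi <- fit$eyo_range[2]
  pred <- predict_trajectories(fit, hi)
  val <- setNames(pred$fit, pred$group)
  expect_gt(val[["SMC_AD"]], val[["SMC_MCI"]])
  expect_gt(val[["SMC_MCI"]], val[["CTR"]])
})

test_that("stochastic slope differences are detected and nulls stay calibrated", {
  det <- sapply(1:25, function(r) {
    d <- simulate_trajectory_data(n_per_group = 40,
                                  slopes = c(CTR = 0, SMC = 0.01),
                                  noise_sd = 0.03, seed = 7000 + r)
    fit <- fit_trajectory_model(d, "three_group")
    it <- fit$interaction_tests
    it$p[it$group == "SMC"] < 0.05 && it$estimate[it$group == "SMC"] > 0
  })
  expect_gte(mean(det), 0.8)

  rej <- sapply(1:40, function(r) {
    d <- simulate_trajectory_data(n_per_group = 40,
                                  slopes = c(CTR = 0.002, SMC = 0.002),
                                  noise_sd = 0.03, seed = 8000 + r)
    fit <- fit_trajectory_model(d, "three_group")
    fit$interaction_tests$p[1] < 0.05
  })
  expect_lte(mean(rej), 0.15)
})

test_that("dropping the interaction from null data barely changes the GCV score", {
  diffs <- sapply(1:10, function(r) {
    d <- simulate_trajectory_data(n_per_group = 40,
                                  slopes = c(CTR = 0.002, SMC = 0.002),
                                  noise_sd = 0.03, seed = 8100 + r)
    full <- fit_trajectory_model(d, "three_group")
    reduced <- mgcv::gam(
      cai ~ s(eyo_years, bs = "ps", k = 10, m = c(2, 2)) + traj_group +
        age_years + sex,
      data = transform(d,
                       traj_group = factor(group, levels = c("CTR", "SMC")),
                       sex = factor(sex, levels = c("female", "male"))),
      method = "GCV.Cp"
    )
    (full$gcv - reduced$gcv.ubre) / reduced$gcv.ubre
  })
  expect_lt(abs(mean(diffs)), 0.05)
})
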