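test_that("burden is the logistic curve with the stated midpoint and asymptotes", {
  expect_equal(burden(-5, -5, 3), 0.5)
  expect_equal(burden(-2, -5, 3), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(burden(-1e6, -5, 3), 0)
  expect_equal(burden(1e6, -5, 3), 1)
  eyo <- seq(-30, 20, by = 0.5)
  expect_true(all(diff(burden(eyo, -5, 3)) > 0))
  expect_error(burden(0, 0, -1), class = "cortasym_domain_error")
})

test_that("generation is deterministic given the seed and honours group counts", {
  cfg <- small_synth(seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(small_synth(seed = 124))
  expect_false(identical(a$thickness$thickness_mm, c2$thickness$thickness_mm))

  cfg2 <- synthetic_config(
    "dian_like", n_per_group = c(CTR = 10L, AMC = 10L, SMC_MCI = 5L, SMC_AD = 5L),
    n_visits = 1L, seed = 2
  )
  coh <- generate_cohort(cfg2)
  base <- coh$metadata[coh$metadata$visit == 0, ]
  expect_equal(nrow(base), 30)
  expect_equal(as.vector(table(base$group)[c("CTR", "AMC", "SMC")]), c(10, 10, 10))
  expect_equal(sum(base$smc_subgroup == "SMC_MCI"), 5)
  expect_true(all(base$cdr[base$group %in% c("CTR", "AMC")] == 0))
  expect_true(all(base$cdr[base$smc_subgroup == "SMC_MCI"] == 0.5))
  expect_true(all(base$cdr[base$smc_subgroup == "SMC_AD"] >= 1))
  expect_true(all(base$mutation_gene[base$group == "CTR"] == "none"))
  expect_true(all(base$mutation_gene[base$group != "CTR"] != "none"))
})

test_that("invalid configs are rejected before any sampling", {
  expect_error(synthetic_config(n_per_group = c(CTR = 5L)),
               class = "cortasym_validation_error")
  expect_error(synthetic_config(n_visits = 9),
               class = "cortasym_validation_error")
  expect_error(synthetic_config(left_thinning_excess = -0.1),
               class = "cortasym_validation_error")
  expect_error(
    synthetic_config(apoe_frequencies = c("3/3" = 0.5, "3/4" = 0.4)),
    class = "cortasym_validation_error"
  )
})

test_that("without noise, controls have exactly symmetric hemispheres and carriers do not", {
  cfg <- synthetic_config(
    "dian_like", n_per_group = c(CTR = 6L, AMC = 6L, SMC_MCI = 4L, SMC_AD = 4L),
    measurement_noise_sd_mm = 0, n_visits = 1L, seed = 9
  )
  at <- build_analysis_table(generate_cohort(cfg))
  expect_true(all(at$cai[at$group == "CTR"] < 1e-12))
  # asymmetry needs enough burden for the shifted values to cross bin edges
  late <- at$smc_subgroup == "SMC_AD" & at$eyo_years > 0
  expect_gt(sum(late), 0)
  expect_true(all(at$cai[late] > 0))
})

test_that("mean CAI orders SMC_AD > SMC_MCI > AMC and biomarkers track burden", {
  reps <- lapply(1:8, function(r) {
    cfg <- synthetic_config(
      "dian_like",
      n_per_group = c(CTR = 40L, AMC = 40L, SMC_MCI = 30L, SMC_AD = 30L),
      n_visits = 1L, seed = 500 + r
    )
    at <- build_analysis_table(generate_cohort(cfg))
    tapply(at$cai, ifelse(at$smc_subgroup == "none", at$group, at$smc_subgroup),
           mean)
  })
  m <- colMeans(do.call(rbind, reps))
  expect_gt(m[["SMC_AD"]], m[["SMC_MCI"]])
  expect_gt(m[["SMC_MCI"]], m[["AMC"]])

  cfg <- synthetic_config(
    "dian_like", n_per_group = c(CTR = 125L, AMC = 125L, SMC_MCI = 125L,
                                 SMC_AD = 125L),
    n_visits = 1L, seed = 77
  )
  meta <- generate_cohort(cfg)$metadata
  carr <- meta[meta$group != "CTR", ]
  b <- burden(carr$eyo_years)
  expect_gt(cor(b, carr$plasma_nfl_pg_ml, method = "spearman"), 0)
  expect_lt(cor(b, carr$mmse, method = "spearman"), 0)
})

test_that("EYO and age advance by exactly the visit interval along follow-ups", {
  coh <- generate_cohort(small_synth(seed = 6))
  meta <- coh$metadata
  for (pid in unique(meta$participant_id)) {
    rows <- meta[meta$participant_id == pid, ]
    rows <- rows[order(rows$visit), ]
    if (nrow(rows) > 1) {
      expect_equal(diff(rows$eyo_years), rep(1, nrow(rows) - 1), tolerance = 1e-12)
      expect_equal(diff(rows$age_years), rep(1, nrow(rows) - 1), tolerance = 1e-12)
    }
  }
  expect_true(all(tapply(meta$visit, meta$participant_id, min) == 0))
})

test_that("delta = 0 yields no systematic SMC-CTR CAI difference", {
  diffs <- sapply(1:12, function(r) {
    cfg <- synthetic_config(
      "dian_like",
      n_per_group = c(CTR = 40L, AMC = 10L, SMC_MCI = 20L, SMC_AD = 20L),
      left_thinning_excess = 0, n_visits = 1L, seed = 900 + r
    )
    at <- build_analysis_table(generate_cohort(cfg))
    mean(at$cai[at$group == "SMC"]) - mean(at$cai[at$group == "CTR"])
  })
  # mean difference within Monte-Carlo error of zero
  expect_lt(abs(mean(diffs)) / (sd(diffs) / sqrt(length(diffs))), 3)
})
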