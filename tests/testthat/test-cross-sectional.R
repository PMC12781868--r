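test_that("Freedman-Lane p approximates the exhaustive two-group enumeration", {
  # n = 6, perfect separation, constant covariates: only the 2 extreme
  # labelings of the C(6,3) = 20 reach the maximal F, and all 6!-permutation
  # draws hit them with probability 72/720 = 0.1
  y <- c(1, 2, 3, 11, 12, 13)
  g <- factor(rep(c("a", "b"), each = 3))
  res <- adjusted_permutation_test(y, g, NULL, n_permutations = 9999, seed = 5)
  expect_lt(abs(res$p_value - 0.1), 0.01)
  expect_gte(res$p_value, 1 / (res$n_permutations + 1))
})

test_that("permutation p is invariant to affine rescaling of the response", {
  set.seed(1)
  n <- 40
  y <- rnorm(n)
  g <- factor(rep(c("a", "b"), n / 2))
  cov <- data.frame(age = rnorm(n, 40, 10), sex = sample(c("male", "female"), n, TRUE))
  a <- adjusted_permutation_test(y, g, cov, 999, seed = 3)
  b <- adjusted_permutation_test(100 + 7 * y, g, cov, 999, seed = 3)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$statistic_observed, b$statistic_observed, tolerance = 1e-9)
})

test_that("permutation test rejects degenerate inputs", {
  y <- rnorm(10)
  expect_error(adjusted_permutation_test(y, factor(rep("a", 10)), NULL, 999),
               class = "cortasym_contract_error")
  expect_error(
    adjusted_permutation_test(y, factor(rep(c("a", "b"), 5)), NULL, 50),
    class = "cortasym_validation_error"
  )
})

test_that("covariates aliased with the group design are dropped, not fatal", {
  set.seed(91)
  n <- 24
  g <- factor(rep(c("AMC", "SMC"), each = n / 2))
  cdr <- ifelse(g == "SMC", 0.5, 0) # exactly separates the groups
  age <- rnorm(n, 45, 8)
  y <- 0.3 + 0.03 * (g == "SMC") + rnorm(n, 0, 0.04)
  expect_warning(
    res <- adjusted_permutation_test(y, g, data.frame(age = age, cdr = cdr),
                                     999, seed = 2),
    "aliased"
  )
  ref <- adjusted_permutation_test(y, g, data.frame(age = age), 999, seed = 2)
  expect_equal(res$statistic_observed, ref$statistic_observed, tolerance = 1e-9)
  expect_equal(res$p_value, ref$p_value)

  # single-level factor covariates are likewise dropped
  expect_warning(
    adjusted_permutation_test(y, g, data.frame(sex = rep("female", n)), 999, 1),
    "single-level"
  )
})

test_that("permutation and ANCOVA agree under zero covariate effects with a true group effect", {
  agree <- sapply(1:40, function(r) {
    set.seed(3000 + r)
    n <- 60
    g <- factor(rep(c("CTR", "SMC"), each = n / 2))
    cov <- data.frame(age = rnorm(n, 40, 10), eyo = rnorm(n, -5, 8))
    y <- 0.35 + 0.04 * (g == "SMC") + rnorm(n, 0, 0.06)
    p1 <- adjusted_permutation_test(y, g, cov, 999, seed = r)$p_value
    p2 <- ancova_group_test(y, g, cov)$p
    (p1 < 0.05) == (p2 < 0.05)
  })
  expect_gte(mean(agree), 0.9)
})

test_that("ANCOVA group F reduces to the textbook one-way F without covariate effects", {
  set.seed(9)
  y <- rnorm(45, 1, 0.3)
  g <- factor(rep(c("a", "b", "c"), each = 15))
  res <- ancova_group_test(y, g, NULL)
  expect_equal(res$F, oracle_anova_f(y, g), tolerance = 1e-9)

  # identical response across groups: F = 0, p = 1
  res0 <- suppressWarnings( # degenerate perfect fit warns inside lm/emmeans
    ancova_group_test(rep(2, 30), factor(rep(c("a", "b"), 15)), NULL)
  )
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)

  # collinear duplicate covariate -> informative rank-deficiency error
  cov <- data.frame(age = rnorm(45), age_copy = 0)
  cov$age_copy <- cov$age
  expect_error(ancova_group_test(y, g, cov), "alias",
               class = "cortasym_validation_error")
})

test_that("ANCOVA pairwise contrasts form one BH family", {
  set.seed(10)
  n <- 90
  g <- factor(rep(c("CTR", "AMC", "SMC"), each = 30))
  y <- 0.3 + 0.05 * (g == "SMC") + rnorm(n, 0, 0.05)
  cov <- data.frame(age = rnorm(n, 40, 8))
  res <- ancova_group_test(y, g, cov)
  expect_equal(nrow(res$pairwise), 3)
  expect_equal(res$pairwise$p_adjusted, oracle_bh(res$pairwise$p_raw),
               tolerance = 1e-12)
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(2)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= 0 & adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "cortasym_domain_error")
})

test_that("ROC AUC equals brute-force pair counting and handles the stated examples", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(F, F, T, T))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), c(T, T, F, F, F, F))$auc, 0.5)
  # positives {1, 4} vs negatives {2, 3}: 2 concordant of 4 pairs
  expect_equal(roc_auc(c(1, 2, 3, 4), c(T, F, F, T))$auc,
               oracle_auc(c(1, 2, 3, 4), c(T, F, F, T)))
  expect_equal(roc_auc(c(1, 2, 3, 4), c(T, F, F, T))$auc, 0.5)
  set.seed(3)
  for (i in 1:30) {
    n <- sample(6:25, 1)
    score <- sample(seq(0, 2, by = 0.25), n, replace = TRUE) # forces ties
    pos <- runif(n) < 0.4
    if (sum(pos) == 0 || sum(!pos) == 0) next
    expect_equal(roc_auc(score, pos)$auc, oracle_auc(score, pos),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4)), class = "cortasym_contract_error")
})

test_that("roc_auc agrees with pROC on continuous scores", {
  skip_if_not_installed("pROC")
  set.seed(4)
  score <- rnorm(60)
  pos <- runif(60) < 0.5
  expect_equal(
    roc_auc(score, pos)$auc,
    as.numeric(pROC::auc(pROC::roc(pos, score, quiet = TRUE, direction = "<"))),
    tolerance = 1e-12
  )
})

test_that("roc_battery negates hippocampal volume so higher is disease-like", {
  at <- build_analysis_table(generate_cohort(small_synth(seed = 44)))
  roc <- roc_battery(at, "SMC", "CTR")
  expect_setequal(roc$marker,
                  c("cai", "hippocampal_volume", "nfl_csf", "nfl_plasma"))
  # NfL separates strongly by construction; hippocampal AUC must be oriented
  # above 0.5, which only happens with the negation
  expect_gt(roc$auc[roc$marker == "nfl_csf"], 0.8)
  expect_gt(roc$auc[roc$marker == "hippocampal_volume"], 0.5)
})

test_that("demographics table reports mean (SD), Fisher p matching enumeration, and flags constants", {
  # 2x2 table ((3,1),(1,3)): two-sided Fisher p = 34/70
  demo_meta <- tibble::tibble(
    participant_id = sprintf("p%d", 1:8),
    cohort = "barcelona_like",
    group = rep(c("CTR", "AMC"), each = 4),
    smc_subgroup = "none",
    sex = c("male", "male", "male", "female", "male", "female", "female", "female"),
    age_years = 40, eyo_years = -5, cdr = 0, visit = 0L, cai = 0.3
  )
  expect_equal(oracle_fisher_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)), 34 / 70,
               tolerance = 1e-12)
  tab <- suppressWarnings(
    demographics_table(demo_meta, "kruskal_wallis",
                       continuous = "age_years", discrete = "sex")
  )
  expect_warning(
    demographics_table(demo_meta, "kruskal_wallis",
                       continuous = "age_years", discrete = "sex"),
    "single distinct value"
  )
  expect_equal(tab$p_value[tab$variable == "sex"], 34 / 70, tolerance = 1e-12)
  expect_true(is.na(tab$p_value[tab$variable == "age_years"]))

  at <- build_analysis_table(generate_cohort(small_synth(seed = 2)))
  tab2 <- demographics_table(at, "anova")
  expect_true(all(c("CTR", "AMC", "SMC") %in% names(tab2)))
  expect_match(tab2$CTR[tab2$variable == "age_years"], "^[0-9.]+ \\([0-9.]+\\)$")
  expect_lt(tab2$p_value[tab2$variable == "csf_nfl_pg_ml"], 0.05)
})

test_that("ANOVA null p-values are approximately uniform", {
  set.seed(12)
  ps <- replicate(400, {
    y <- rnorm(30)
    g <- factor(rep(c("a", "b", "c"), each = 10))
    summary(aov(y ~ g))[[1]]$`Pr(>F)`[1]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("APOE-stratified tests run on carriers with age/sex/EYO/CDR adjustment", {
  cfg <- synthetic_config(
    "dian_like",
    n_per_group = c(CTR = 30L, AMC = 60L, SMC_MCI = 30L, SMC_AD = 30L),
    n_visits = 1L, seed = 15
  )
  at <- build_analysis_table(generate_cohort(cfg))
  res <- apoe_stratified_tests(at, n_permutations = 499, seed = 3, min_n = 10)
  expect_s3_class(res$across_genotypes, "permutation_result")
  expect_identical(res$across_genotypes$covariates,
                   c("age_years", "sex", "eyo_years", "cdr"))
  expect_true(all(res$within_genotype$n >= 10))
  ok <- !is.na(res$within_genotype$p_raw)
  expect_equal(res$within_genotype$p_adjusted[ok],
               oracle_bh(res$within_genotype$p_raw[ok]), tolerance = 1e-12)
})
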