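#' Covariate-adjusted permutation test (Freedman-Lane)
#'
#' Tests a group factor's effect on a response while adjusting for nuisance
#' covariates, using the Freedman-Lane residual-permutation scheme: the
#' covariate-only (reduced) linear model is fitted, its residuals are
#' permuted and added back to its fitted values, and the full model
#' (group + covariates) is refitted on each permuted pseudo-response. The
#' statistic is the partial F for the group factor; the p-value is
#' `(1 + #permuted F >= observed F) / (n_permutations + 1)`.
#'
#' @param y Numeric response vector (here, CAI).
#' @param group Factor (or coercible) with at least two levels, each with at
#'   least two observations.
#' @param covariates Data frame of nuisance covariates (e.g. age, sex, EYO,
#'   optionally CDR); factors are expanded via `model.matrix`. May be `NULL`
#'   or zero-column for an unadjusted test. Covariate columns that carry no
#'   information in the subset at hand — single-level factors, or columns
#'   aliased with the intercept-plus-group design (e.g. CDR inside a stratum
#'   where it exactly separates the groups) — are dropped with a warning.
#' @param n_permutations Number of random permutations (>= 99). Default 9999.
#' @param seed Integer seed recorded in the result; permutations are drawn
#'   under it without disturbing the caller's RNG.
#' @return A list of class `permutation_result`: `statistic_observed` (F),
#'   `p_value`, `n_permutations`, `seed`, `covariates`, `df`.
#' @export
adjusted_permutation_test <- function(y, group, covariates = NULL,
                                      n_permutations = 9999L, seed = 1L) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) {
    stop_contract("`group` must have at least two levels, got %d", nlevels(group))
  }
  if (any(table(group) < 2L)) {
    stop_contract("every group level needs at least two observations")
  }
  if (n_permutations < 99L) {
    stop_validation("`n_permutations` must be at least 99")
  }
  n <- length(y)
  if (length(group) != n) stop_contract("`y` and `group` lengths differ")
  if (any(!is.finite(y))) {
    stop_contract("`y` must be complete; apply pairwise deletion first")
  }

  covariates <- prepare_covariates(covariates, n)
  G <- model.matrix(~group)[, -1, drop = FALSE]
  C <- covariates$matrix
  # covariate columns that are aliased given the intercept and the group
  # dummies (e.g. CDR inside a stratum where it separates the groups) carry
  # no adjustment information and make the group F undefined: drop them
  q_prio <- qr(cbind(1, G, C))
  if (q_prio$rank < ncol(C) + ncol(G) + 1L) {
    dep <- q_prio$pivot[(q_prio$rank + 1L):(ncol(C) + ncol(G) + 1L)]
    if (any(dep <= ncol(G) + 1L)) {
      stop_validation("group factor is aliased with the covariates")
    }
    drop_cols <- dep - ncol(G) - 1L
    rlang::warn(sprintf(
      "dropping covariate column(s) aliased with the design: %s",
      paste(colnames(C)[drop_cols], collapse = ", ")
    ))
    C <- C[, -drop_cols, drop = FALSE]
  }
  X_red <- cbind(`(Intercept)` = rep(1, n), C)
  X_full <- cbind(X_red, G)
  q_red <- qr(X_red)
  q_full <- qr(X_full)
  if (q_full$rank < ncol(X_full)) {
    stop_validation("full design matrix is rank deficient")
  }
  df1 <- ncol(X_full) - ncol(X_red)
  df2 <- n - ncol(X_full)
  if (df2 < 1) stop_validation("not enough observations for the design")

  Q_red <- qr.Q(q_red)
  Q_full <- qr.Q(q_full)

  f_stat <- function(Y) {
    # Y: n x m matrix of responses; partial F per column via projections
    tot <- colSums(Y^2)
    rss_red <- tot - colSums((crossprod(Q_red, Y))^2)
    rss_full <- tot - colSums((crossprod(Q_full, Y))^2)
    ((rss_red - rss_full) / df1) / (rss_full / df2)
  }

  f_obs <- f_stat(matrix(y, ncol = 1))
  fitted_red <- Q_red %*% crossprod(Q_red, y)
  resid_red <- y - fitted_red

  f_perm <- with_seed(seed, {
    perm_idx <- replicate(n_permutations, sample.int(n))
    Y_perm <- matrix(resid_red[perm_idx], nrow = n) + as.vector(fitted_red)
    f_stat(Y_perm)
  })

  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (n_permutations + 1)
  structure(
    list(
      statistic_observed = as.numeric(f_obs),
      p_value = p,
      n_permutations = as.integer(n_permutations),
      seed = as.integer(seed),
      covariates = covariates$names,
      df = c(df1 = df1, df2 = df2)
    ),
    class = "permutation_result"
  )
}

prepare_covariates <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0)) {
    return(list(matrix = matrix(numeric(0), nrow = n, ncol = 0), names = character(0)))
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) stop_contract("covariate rows must match length(y)")
  if (anyNA(covariates)) {
    stop_contract("covariates must be complete; apply pairwise deletion first")
  }
  # sex and other character columns become factors; female is the reference
  single_level <- character(0)
  for (j in seq_along(covariates)) {
    if (is.character(covariates[[j]])) {
      lev <- sort(unique(covariates[[j]]))
      covariates[[j]] <- factor(covariates[[j]], levels = lev)
    }
    if (is.factor(covariates[[j]]) && nlevels(droplevels(covariates[[j]])) < 2L) {
      single_level <- c(single_level, names(covariates)[j])
    }
  }
  if (length(single_level) > 0) {
    rlang::warn(sprintf(
      "dropping single-level covariate(s): %s", paste(single_level, collapse = ", ")
    ))
    covariates <- covariates[, setdiff(names(covariates), single_level),
                             drop = FALSE]
  }
  if (ncol(covariates) == 0) {
    return(list(matrix = matrix(numeric(0), nrow = n, ncol = 0),
                names = character(0)))
  }
  mm <- model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  list(matrix = mm, names = names(covariates))
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Freedman-Lane permutation test: F(%d, %d) = %.4g, p = %.4g (%d permutations, covariates: %s)\n",
    x$df["df1"], x$df["df2"], x$statistic_observed, x$p_value,
    x$n_permutations,
    if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "none"
  ))
  invisible(x)
}

#' ANCOVA group test with BH-corrected pairwise contrasts
#'
#' Ordinary least-squares fit of `y ~ group + covariates`; the group effect is
#' the partial F comparing against the covariate-only model, and pairwise
#' group contrasts are the model's estimated marginal mean differences
#' (via emmeans) with Benjamini-Hochberg adjustment across the contrast
#' family.
#'
#' @inheritParams adjusted_permutation_test
#' @return List with `F`, `p`, `df`, `pairwise` (tibble: group_a, group_b,
#'   estimate, p_raw, p_adjusted) and the fitted `model`.
#' @export
ancova_group_test <- function(y, group, covariates = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop_contract("`group` must have at least two levels")
  n <- length(y)
  dat <- data.frame(.y = y, group = group)
  cov_names <- character(0)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop_contract("covariate rows must match length(y)")
    cov_names <- names(covariates)
    dat <- cbind(dat, covariates)
  }
  rhs_red <- if (length(cov_names)) paste(cov_names, collapse = " + ") else "1"
  fit_full <- lm(as.formula(paste(".y ~ group +", rhs_red)), data = dat)
  if (any(is.na(coef(fit_full)))) {
    stop_validation(
      "design matrix is rank deficient; aliased column(s): %s",
      paste(names(coef(fit_full))[is.na(coef(fit_full))], collapse = ", ")
    )
  }
  fit_red <- lm(as.formula(paste(".y ~", rhs_red)), data = dat)
  an <- anova(fit_red, fit_full)
  Fv <- an$F[2]
  pv <- an$`Pr(>F)`[2]
  # the reduced model already fits perfectly (e.g. identical y): the group
  # sum of squares is numerical noise, so F is 0 by convention
  ss_total <- sum((y - mean(y))^2)
  if (is.na(Fv) || an$`Sum of Sq`[2] <= 1e-12 * (ss_total + 1e-12)) {
    Fv <- 0
    pv <- 1
  }

  emm <- emmeans::emmeans(fit_full, "group")
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "none"))
  labels <- strsplit(as.character(prs$contrast), " - ")
  p_raw <- prs$p.value
  p_raw[is.na(p_raw)] <- 1
  pairwise <- tibble::tibble(
    group_a = vapply(labels, `[`, "", 1),
    group_b = vapply(labels, `[`, "", 2),
    estimate = prs$estimate,
    p_raw = p_raw,
    p_adjusted = bh_adjust(p_raw)
  )
  list(F = Fv, p = pv, df = c(an$Df[2], an$Res.Df[2]), pairwise = pairwise,
       model = fit_full)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (same order as input), capped at 1 and monotone
#'   non-decreasing in raw rank.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03)) # all 0.03
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_domain("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' ROC area under the curve by the Mann-Whitney identity
#'
#' AUC is the fraction of (positive, negative) pairs in which the positive
#' case scores higher, ties counting one half — computed from ranks, which is
#' exactly the normalized Mann-Whitney U.
#'
#' @param score Numeric marker values, oriented so larger means more
#'   disease-like (negate hippocampal volume before calling; see
#'   [roc_battery()]).
#' @param is_positive Logical vector: `TRUE` for the positive (disease) class.
#' @param marker Optional marker name carried into the result.
#' @param positive_label Optional label for the positive class.
#' @return A list of class `roc_result`: `auc`, `marker`, `positive_label`,
#'   `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc # 1
roc_auc <- function(score, is_positive, marker = "marker",
                    positive_label = "positive") {
  if (length(score) != length(is_positive)) {
    stop_contract("`score` and `is_positive` lengths differ")
  }
  keep <- is.finite(score) & !is.na(is_positive)
  score <- score[keep]
  is_positive <- as.logical(is_positive[keep])
  n_pos <- sum(is_positive)
  n_neg <- sum(!is_positive)
  if (n_pos == 0 || n_neg == 0) {
    stop_contract("both classes must be present (got %d positive, %d negative)",
                  n_pos, n_neg)
  }
  r <- rank(score) # midranks handle ties as half-pairs
  u <- sum(r[is_positive]) - n_pos * (n_pos + 1) / 2
  structure(
    list(
      auc = u / (n_pos * n_neg),
      marker = marker,
      positive_label = positive_label,
      n_pos = n_pos,
      n_neg = n_neg
    ),
    class = "roc_result"
  )
}

#' ROC comparison of CAI against the reference biomarkers
#'
#' Computes one AUC per marker for a two-group contrast of the analysis
#' table. All markers are oriented so that higher is more disease-like
#' before the AUC: hippocampal volume is negated, the others (CAI, CSF NfL,
#' plasma NfL) are used as-is.
#'
#' @param analysis Analysis table (baseline rows are selected internally).
#' @param positive,negative Group labels, e.g. `"SMC"`, `"CTR"`; SMC
#'   subgroups (`"SMC_MCI"`, `"SMC_AD"`) are also accepted.
#' @param markers Character vector among `cai`, `hippocampal_volume`,
#'   `nfl_csf`, `nfl_plasma`.
#' @return Tibble: marker, auc, n_pos, n_neg.
#' @export
roc_battery <- function(analysis, positive = "SMC", negative = "CTR",
                        markers = c("cai", "hippocampal_volume", "nfl_csf",
                                    "nfl_plasma")) {
  base <- analysis[analysis$visit == 0L, ]
  lab <- ifelse(base$smc_subgroup != "none" &
                  base$smc_subgroup %in% c(positive, negative),
                base$smc_subgroup, base$group)
  cols <- c(cai = "cai", hippocampal_volume = "hippocampal_volume_mm3",
            nfl_csf = "csf_nfl_pg_ml", nfl_plasma = "plasma_nfl_pg_ml")
  res <- lapply(markers, function(m) {
    keep <- lab %in% c(positive, negative)
    score <- base[[cols[[m]]]][keep]
    if (m == "hippocampal_volume") score <- -score
    r <- roc_auc(score, lab[keep] == positive, marker = m,
                 positive_label = positive)
    tibble::tibble(marker = m, positive = positive, negative = negative,
                   auc = r$auc, n_pos = r$n_pos, n_neg = r$n_neg)
  })
  dplyr::bind_rows(res)
}

#' Group demographics table with per-variable tests
#'
#' Continuous variables are summarised as "mean (SD)" per group and tested
#' with Kruskal-Wallis (small single-centre cohorts) or one-way ANOVA (large
#' cohorts); discrete variables are cross-tabulated and tested with Fisher's
#' exact test (with a seeded Monte-Carlo fallback for large tables).
#' Variables with a single distinct value get a missing p-value and a
#' warning.
#'
#' @param analysis Analysis table; baseline rows are used.
#' @param continuous_test `"kruskal_wallis"` or `"anova"`.
#' @param continuous,discrete Variable names to summarise.
#' @param fisher_sim_threshold Total cell count above which Fisher's p is
#'   Monte-Carlo simulated (seeded) instead of enumerated.
#' @param seed Seed for the simulated Fisher fallback.
#' @return Tibble: variable, type, one summary column per group, p_value.
#' @export
demographics_table <- function(analysis,
                               continuous_test = c("kruskal_wallis", "anova"),
                               continuous = c("age_years", "eyo_years", "mmse",
                                              "csf_nfl_pg_ml", "plasma_nfl_pg_ml"),
                               discrete = c("sex", "apoe_e4_carrier"),
                               fisher_sim_threshold = 2000L,
                               seed = 1L) {
  continuous_test <- match.arg(continuous_test)
  base <- analysis[analysis$visit == 0L, ]
  grp <- droplevels(factor(base$group, levels = c("CTR", "AMC", "SMC")))
  if (nlevels(grp) < 2L) stop_contract("need at least two groups")
  rows <- list()
  for (v in continuous) {
    if (!v %in% names(base)) next
    x <- base[[v]]
    ok <- is.finite(x)
    summ <- tapply(x[ok], grp[ok], function(z) {
      sprintf("%.1f (%.1f)", mean(z), sd(z))
    })
    if (length(unique(x[ok])) < 2L) {
      rlang::warn(sprintf("variable %s has a single distinct value; p set to NA", v))
      p <- NA_real_
    } else if (continuous_test == "kruskal_wallis") {
      p <- kruskal.test(x[ok], grp[ok])$p.value
    } else {
      p <- summary(aov(x[ok] ~ grp[ok]))[[1]]$`Pr(>F)`[1]
    }
    rows[[v]] <- c(list(variable = v, type = "continuous"),
                   as.list(summ), list(p_value = p))
  }
  for (v in discrete) {
    if (!v %in% names(base)) next
    x <- base[[v]]
    ok <- !is.na(x)
    tab <- table(x[ok], grp[ok])
    summ <- apply(tab, 2, function(col) paste(col, collapse = "/"))
    if (nrow(tab) < 2L) {
      rlang::warn(sprintf("variable %s has a single distinct value; p set to NA", v))
      p <- NA_real_
    } else if (sum(tab) > fisher_sim_threshold) {
      p <- with_seed(seed, fisher.test(tab, simulate.p.value = TRUE, B = 1e4)$p.value)
    } else {
      p <- tryCatch(
        fisher.test(tab, workspace = 2e6)$p.value,
        error = function(e) {
          with_seed(seed, fisher.test(tab, simulate.p.value = TRUE, B = 1e4)$p.value)
        }
      )
    }
    rows[[v]] <- c(list(variable = v, type = "discrete"),
                   as.list(summ), list(p_value = p))
  }
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

#' Pairwise group comparisons of CAI with permutation tests
#'
#' Runs [adjusted_permutation_test()] for every pair of group levels and
#' BH-adjusts the pairwise p-values as one family.
#'
#' @inheritParams adjusted_permutation_test
#' @return A `group_comparison_report`: tibble with group_a, group_b, F,
#'   p_raw, p_adjusted, plus attributes `method`, `seed`.
#' @export
pairwise_permutation_tests <- function(y, group, covariates = NULL,
                                       n_permutations = 9999L, seed = 1L) {
  group <- droplevels(as.factor(group))
  levs <- levels(group)
  if (length(levs) < 2L) stop_contract("need at least two groups")
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  res <- lapply(seq_along(pairs), function(k) {
    pr <- pairs[[k]]
    keep <- group %in% pr
    cov_k <- if (is.null(covariates)) NULL else
      as.data.frame(covariates)[keep, , drop = FALSE]
    t <- adjusted_permutation_test(y[keep], group[keep], cov_k,
                                   n_permutations, seed + k)
    tibble::tibble(group_a = pr[1], group_b = pr[2],
                   F = t$statistic_observed, p_raw = t$p_value)
  })
  out <- dplyr::bind_rows(res)
  out$p_adjusted <- bh_adjust(out$p_raw)
  attr(out, "method") <- "permutation"
  attr(out, "seed") <- seed
  out
}

#' APOE-stratified CAI comparisons in mutation carriers
#'
#' Baseline mutation carriers only. Two question families, each adjusted by
#' age, sex, EYO and CDR with Freedman-Lane permutation tests: (1) CAI
#' differences across APOE genotypes (overall F over genotype strata with at
#' least `min_n` carriers), and (2) AMC vs SMC within each such genotype
#' stratum, BH-corrected as one family.
#'
#' @param analysis Analysis table.
#' @param n_permutations,seed Passed to [adjusted_permutation_test()].
#' @param min_n Minimum carriers per genotype stratum. Default 10.
#' @return List with `across_genotypes` (permutation_result or NULL) and
#'   `within_genotype` (tibble: genotype, F, p_raw, p_adjusted, n).
#' @export
apoe_stratified_tests <- function(analysis, n_permutations = 9999L, seed = 1L,
                                  min_n = 10L) {
  base <- analysis[analysis$visit == 0L & analysis$group %in% c("AMC", "SMC") &
                     !is.na(analysis$apoe_genotype) & is.finite(analysis$cai), ]
  covars <- c("age_years", "sex", "eyo_years", "cdr")
  counts <- table(base$apoe_genotype)
  keep_gt <- names(counts)[counts >= min_n]
  across <- NULL
  if (length(keep_gt) >= 2L) {
    sub <- base[base$apoe_genotype %in% keep_gt, ]
    across <- adjusted_permutation_test(
      sub$cai, sub$apoe_genotype, sub[, covars], n_permutations, seed
    )
  }
  within <- lapply(keep_gt, function(gt) {
    sub <- base[base$apoe_genotype == gt, ]
    if (length(unique(sub$group)) < 2L || any(table(sub$group) < 2L)) {
      return(tibble::tibble(genotype = gt, F = NA_real_, p_raw = NA_real_,
                            n = nrow(sub)))
    }
    t <- adjusted_permutation_test(sub$cai, sub$group, sub[, covars],
                                   n_permutations, seed + match(gt, keep_gt))
    tibble::tibble(genotype = gt, F = t$statistic_observed, p_raw = t$p_value,
                   n = nrow(sub))
  })
  within <- dplyr::bind_rows(within)
  if (nrow(within) > 0) {
    ok <- !is.na(within$p_raw)
    within$p_adjusted <- NA_real_
    within$p_adjusted[ok] <- bh_adjust(within$p_raw[ok])
  }
  list(across_genotypes = across, within_genotype = within)
}
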