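#' Run configuration for the full pipeline
#'
#' Exactly one input source must be given: either paths to real tables
#' (`metadata_path` + `thickness_path`) or a [synthetic_config()].
#'
#' @param synthetic A [synthetic_config()], or `NULL`.
#' @param metadata_path,thickness_path Paths to a metadata CSV and a long
#'   thickness CSV, or `NULL`.
#' @param thickness_dialect Dialect for [read_thickness()].
#' @param cai A [cai_config()].
#' @param analyses Character subset of `c("cross_sectional", "associations",
#'   "longitudinal", "apoe_stratified")`.
#' @param grouping Grouping for the longitudinal model.
#' @param n_permutations Permutations for every permutation test.
#' @param seed Master seed; every stage derives its own stream from it.
#' @param out_dir Output directory for the results bundle.
#' @return A list of class `run_config`.
#' @export
run_config <- function(synthetic = NULL,
                       metadata_path = NULL,
                       thickness_path = NULL,
                       thickness_dialect = "long_csv",
                       cai = cai_config(),
                       analyses = c("cross_sectional", "associations",
                                    "longitudinal", "apoe_stratified"),
                       grouping = "three_group",
                       n_permutations = 9999L,
                       seed = 1L,
                       out_dir = tempfile("cortasym_run_")) {
  real <- !is.null(metadata_path) || !is.null(thickness_path)
  if (real && !is.null(synthetic)) {
    stop_validation("supply either real input paths or a synthetic config, not both")
  }
  if (!real && is.null(synthetic)) {
    stop_validation("supply real input paths or a synthetic config")
  }
  if (real && (is.null(metadata_path) || is.null(thickness_path))) {
    stop_validation("real input needs both `metadata_path` and `thickness_path`")
  }
  analyses <- match.arg(analyses, several.ok = TRUE)
  structure(
    list(
      synthetic = synthetic,
      metadata_path = metadata_path,
      thickness_path = thickness_path,
      thickness_dialect = thickness_dialect,
      cai = cai,
      analyses = analyses,
      grouping = grouping,
      n_permutations = as.integer(n_permutations),
      seed = as.integer(seed),
      out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Run the full simulate/ingest -> CAI -> analyze pipeline
#'
#' Executes every configured stage and writes a machine-readable results
#' bundle to `config$out_dir`: `manifest.json` (package version, config
#' hash, seeds, per-stage row counts), `analysis_table.csv`,
#' `demographics.csv`, `group_tests.csv`, `roc.csv`, `correlations.csv`,
#' `apoe_tests.csv`, `gam_interactions.json` and `trajectories.csv`.
#' Deterministic given the config (seeds included), so a rerun reproduces
#' the bundle byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`analysis_table`,
#'   `demographics`, `group_tests`, `roc`, `correlations`, `apoe`,
#'   `gam_fit`, `trajectories`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "cortasym",
    version = as.character(utils::packageVersion("cortasym")),
    config_hash = rlang::hash(unclass(config)[setdiff(names(config), "out_dir")]),
    seed = config$seed,
    n_permutations = config$n_permutations,
    stages = list()
  )
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      manifest$stages[[name]] <- list(status = "failed", error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
  }

  cohort <- stage("ingest", {
    if (!is.null(config$synthetic)) {
      generate_cohort(config$synthetic)
    } else {
      cohort_table(
        read_metadata(config$metadata_path),
        read_thickness(config$thickness_path, config$thickness_dialect)
      )
    }
  })
  manifest$stages$ingest <- list(
    status = "ok", n_participants = length(unique(cohort$metadata$participant_id)),
    n_rows = nrow(cohort$metadata)
  )

  analysis <- stage("cai", build_analysis_table(cohort, config$cai))
  manifest$stages$cai <- list(status = "ok", n_rows = nrow(analysis))
  write_num_csv(analysis, file.path(config$out_dir, "analysis_table.csv"))

  base <- analysis[analysis$visit == 0L, ]
  results <- list(analysis_table = analysis)
  template <- base$cohort[1]

  if ("cross_sectional" %in% config$analyses) {
    res <- stage("cross_sectional", {
      cont_test <- if (identical(template, "dian_like")) "anova" else "kruskal_wallis"
      demo <- demographics_table(analysis, cont_test,
                                 seed = child_seed(config$seed, "cohort"))
      covars <- base[, c("age_years", "sex", "eyo_years")]
      carrier <- factor(ifelse(base$group == "CTR", "CTR", "carriers"),
                        levels = c("CTR", "carriers"))
      overall <- adjusted_permutation_test(
        base$cai, carrier, covars, config$n_permutations,
        child_seed(config$seed, "permutation")
      )
      three <- if (identical(template, "dian_like")) {
        anc <- ancova_group_test(base$cai, base$group, covars)
        tibble::tibble(
          group_a = anc$pairwise$group_a, group_b = anc$pairwise$group_b,
          statistic = anc$pairwise$estimate, p_raw = anc$pairwise$p_raw,
          p_adjusted = anc$pairwise$p_adjusted, method = "ancova_pairwise"
        )
      } else {
        pw <- pairwise_permutation_tests(
          base$cai, base$group, covars, config$n_permutations,
          child_seed(config$seed, "permutation")
        )
        tibble::tibble(
          group_a = pw$group_a, group_b = pw$group_b, statistic = pw$F,
          p_raw = pw$p_raw, p_adjusted = pw$p_adjusted, method = "permutation"
        )
      }
      tests <- dplyr::bind_rows(
        tibble::tibble(group_a = "carriers", group_b = "CTR",
                       statistic = overall$statistic_observed,
                       p_raw = overall$p_value, p_adjusted = overall$p_value,
                       method = "permutation"),
        three
      )
      roc <- dplyr::bind_rows(
        roc_battery(analysis, "SMC", "CTR"),
        roc_battery(analysis, "SMC", "AMC"),
        roc_battery(analysis, "AMC", "CTR")
      )
      list(demo = demo, tests = tests, roc = roc)
    })
    manifest$stages$cross_sectional <- list(status = "ok",
                                            n_tests = nrow(res$tests))
    write_num_csv(res$demo, file.path(config$out_dir, "demographics.csv"))
    write_num_csv(res$tests, file.path(config$out_dir, "group_tests.csv"))
    write_num_csv(res$roc, file.path(config$out_dir, "roc.csv"))
    results$demographics <- res$demo
    results$group_tests <- res$tests
    results$roc <- res$roc
  }

  if ("associations" %in% config$analyses) {
    cors <- stage("associations", association_battery(analysis))
    manifest$stages$associations <- list(status = "ok", n_rows = nrow(cors))
    write_num_csv(cors, file.path(config$out_dir, "correlations.csv"))
    results$correlations <- cors
  }

  if ("apoe_stratified" %in% config$analyses) {
    apoe <- stage("apoe_stratified", {
      apoe_stratified_tests(analysis, config$n_permutations,
                            child_seed(config$seed, "permutation"))
    })
    manifest$stages$apoe_stratified <- list(
      status = "ok",
      across_p = if (is.null(apoe$across_genotypes)) NA else
        apoe$across_genotypes$p_value
    )
    write_num_csv(apoe$within_genotype, file.path(config$out_dir, "apoe_tests.csv"))
    results$apoe <- apoe
  }

  if ("longitudinal" %in% config$analyses &&
      max(analysis$visit, na.rm = TRUE) > 0L) {
    res <- stage("longitudinal", {
      fit <- fit_trajectory_model(analysis, config$grouping)
      grid <- seq(fit$eyo_range[1], fit$eyo_range[2], length.out = 50)
      traj <- predict_trajectories(fit, grid)
      list(fit = fit, traj = traj)
    })
    manifest$stages$longitudinal <- list(
      status = "ok", n_observations = res$fit$n_observations
    )
    jsonlite::write_json(
      lapply(seq_len(nrow(res$fit$interaction_tests)), function(i) {
        as.list(res$fit$interaction_tests[i, ])
      }),
      file.path(config$out_dir, "gam_interactions.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    write_num_csv(res$traj, file.path(config$out_dir, "trajectories.csv"))
    results$gam_fit <- res$fit
    results$trajectories <- res$traj
  }

  manifest$stages <- manifest$stages
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

# CSV writer with stable full-precision numeric formatting, so reruns are
# byte-identical across platforms.
write_num_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- format(df[[j]], digits = 17, trim = TRUE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
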