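#' Read regional cortical thickness tables
#'
#' Two dialects are supported. `aparcstats2table_lh_rh_merged` is the
#' tab-separated wide format produced by merging FreeSurfer's
#' `aparcstats2table` output for both hemispheres: one row per
#' participant-visit, an id column, optionally a `visit` column (0 assumed
#' when absent), and 68 columns named `lh_<region>_thickness` /
#' `rh_<region>_thickness` over the Desikan-Killiany parcels. `long_csv` is a
#' comma-separated table with columns `participant_id`, `visit`,
#' `hemisphere` (`left`/`right`), `region`, `thickness_mm`.
#'
#' @param path Path to the table.
#' @param dialect `"aparcstats2table_lh_rh_merged"` or `"long_csv"`.
#' @return A long thickness tibble with columns `participant_id`, `visit`,
#'   `hemisphere`, `region`, `thickness_mm`, regions in canonical
#'   [dk_regions] order within each participant-visit-hemisphere.
#' @export
read_thickness <- function(path,
                           dialect = c("aparcstats2table_lh_rh_merged", "long_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_validation("file not found: %s", path)

  if (dialect == "aparcstats2table_lh_rh_merged") {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    id_col <- intersect(
      c("participant_id", names(raw)[grepl("^[lr]h\\.aparc", names(raw))][1]),
      names(raw)
    )[1]
    if (is.na(id_col)) {
      stop_validation(
        "no participant id column found (expected `participant_id` or an `lh.aparc.*` first column)"
      )
    }
    expected <- c(
      paste0("lh_", dk_regions, "_thickness"),
      paste0("rh_", dk_regions, "_thickness")
    )
    missing <- setdiff(expected, names(raw))
    if (length(missing) > 0) {
      miss_regions <- unique(gsub("^[lr]h_(.*)_thickness$", "\\1", missing))
      stop_validation(
        "missing thickness column(s) for region(s): %s",
        paste(miss_regions, collapse = ", ")
      )
    }
    long <- tidyr::pivot_longer(
      raw,
      cols = dplyr::all_of(expected),
      names_to = c("hemisphere", "region"),
      names_pattern = "^([lr]h)_(.*)_thickness$",
      values_to = "thickness_mm"
    )
    long$hemisphere <- ifelse(long$hemisphere == "lh", "left", "right")
    long$participant_id <- as.character(long[[id_col]])
    if (!"visit" %in% names(long)) long$visit <- 0L
    long <- long[, c("participant_id", "visit", "hemisphere", "region", "thickness_mm")]
  } else {
    long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    req <- c("participant_id", "visit", "hemisphere", "region", "thickness_mm")
    missing <- setdiff(req, names(long))
    if (length(missing) > 0) {
      stop_validation("long table missing column(s): %s", paste(missing, collapse = ", "))
    }
    long <- long[, req]
    long$participant_id <- as.character(long$participant_id)
  }
  long <- tibble::as_tibble(long)
  long$visit <- as.integer(long$visit)
  long$region <- as.character(long$region)
  validate_thickness(long)
  # normalise region order to the canonical atlas order
  long$region <- factor(long$region, levels = dk_regions)
  long <- dplyr::arrange(
    long, .data$participant_id, .data$visit, .data$hemisphere, .data$region
  )
  long$region <- as.character(long$region)
  long
}

validate_thickness <- function(long) {
  bad_region <- setdiff(unique(long$region), dk_regions)
  if (length(bad_region) > 0) {
    stop_validation(
      "unrecognized region name(s): %s", paste(bad_region, collapse = ", ")
    )
  }
  if (!all(long$hemisphere %in% c("left", "right"))) {
    stop_validation("hemisphere must be 'left' or 'right'")
  }
  bad <- !is.finite(long$thickness_mm) | long$thickness_mm <= 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop_validation(
      "non-positive or non-numeric thickness for participant %s visit %d (%s %s)",
      long$participant_id[i], long$visit[i], long$hemisphere[i], long$region[i]
    )
  }
  if (any(long$visit < 0)) stop_validation("visit indices must be non-negative")
  dup <- duplicated(long[, c("participant_id", "visit", "hemisphere", "region")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop_validation(
      "duplicate thickness entry for participant %s visit %d hemisphere %s",
      long$participant_id[i], long$visit[i], long$hemisphere[i]
    )
  }
  counts <- dplyr::count(long, .data$participant_id, .data$visit, .data$hemisphere)
  if (any(counts$n != 34L)) {
    i <- which(counts$n != 34L)[1]
    stop_validation(
      "participant %s visit %d hemisphere %s has %d regions (expected 34)",
      counts$participant_id[i], counts$visit[i], counts$hemisphere[i], counts$n[i]
    )
  }
  hemi <- dplyr::count(long, .data$participant_id, .data$visit)
  if (any(hemi$n != 68L)) {
    i <- which(hemi$n != 68L)[1]
    stop_validation(
      "participant %s visit %d must have exactly one left and one right profile",
      hemi$participant_id[i], hemi$visit[i]
    )
  }
  invisible(long)
}

#' Write a long thickness table
#'
#' @param thickness Long thickness tibble (see [read_thickness()]).
#' @param path Output path.
#' @param dialect Output dialect; `"long_csv"` (default) round-trips with
#'   [read_thickness()], `"aparcstats2table_lh_rh_merged"` writes the wide
#'   tab-separated layout.
#' @export
write_thickness <- function(thickness, path,
                            dialect = c("long_csv", "aparcstats2table_lh_rh_merged")) {
  dialect <- match.arg(dialect)
  validate_thickness(thickness)
  if (dialect == "long_csv") {
    readr::write_csv(thickness, path, progress = FALSE)
  } else {
    wide <- tidyr::pivot_wider(
      dplyr::mutate(
        thickness,
        col = paste0(
          ifelse(.data$hemisphere == "left", "lh_", "rh_"),
          .data$region, "_thickness"
        )
      )[, c("participant_id", "visit", "col", "thickness_mm")],
      names_from = "col", values_from = "thickness_mm"
    )
    ord <- c(
      "participant_id", "visit",
      paste0("lh_", dk_regions, "_thickness"),
      paste0("rh_", dk_regions, "_thickness")
    )
    readr::write_tsv(wide[, ord], path, progress = FALSE)
  }
  invisible(path)
}

metadata_columns <- c(
  "participant_id", "cohort", "group", "smc_subgroup", "mutation_gene",
  "apoe_genotype", "apoe_e4_carrier", "sex", "age_years",
  "parent_onset_age_years", "eyo_years", "cdr", "mmse", "csf_nfl_pg_ml",
  "plasma_nfl_pg_ml", "hippocampal_volume_mm3", "visit"
)

#' Read and validate a participant metadata table
#'
#' Comma-separated, one row per participant-visit. Required columns:
#' `participant_id`, `group` (CTR/AMC/SMC), `sex` (male/female), `age_years`,
#' `visit`. Optional columns follow the metadata schema (`cdr`, `eyo_years`,
#' `parent_onset_age_years`, `mmse`, `csf_nfl_pg_ml`, `plasma_nfl_pg_ml`,
#' `hippocampal_volume_mm3`, `apoe_genotype`, `mutation_gene`, `cohort`);
#' absent or empty optional values become `NA`. The derived fields
#' `smc_subgroup` (SMC_MCI at CDR 0.5, SMC_AD at CDR >= 1) and
#' `apoe_e4_carrier` (genotype contains a 4 allele) are filled in when not
#' supplied, and the CDR/group consistency rules are enforced: CTR and AMC
#' require CDR 0, SMC requires CDR >= 0.5.
#'
#' @param path Path to the CSV file.
#' @return A validated metadata tibble with the full column set.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("participant_id", "group", "sex", "age_years", "visit")
  missing <- setdiff(req, names(raw))
  if (length(missing) > 0) {
    stop_validation("metadata missing column(s): %s", paste(missing, collapse = ", "))
  }
  validate_metadata(raw)
}

#' Validate (and complete) a metadata table
#'
#' @param meta A data frame of participant records; see [read_metadata()] for
#'   the schema.
#' @return The completed, validated metadata tibble.
#' @export
validate_metadata <- function(meta) {
  meta <- tibble::as_tibble(meta)
  meta$participant_id <- as.character(meta$participant_id)
  for (col in setdiff(metadata_columns, names(meta))) meta[[col]] <- NA
  meta <- meta[, metadata_columns]

  if (!all(meta$group %in% c("CTR", "AMC", "SMC"))) {
    bad <- setdiff(unique(meta$group), c("CTR", "AMC", "SMC"))
    stop_validation("unknown group label(s): %s", paste(bad, collapse = ", "))
  }
  if (!all(meta$sex %in% c("male", "female"))) {
    stop_validation("sex must be 'male' or 'female'")
  }
  meta$visit <- as.integer(meta$visit)
  if (any(is.na(meta$visit)) || any(meta$visit < 0)) {
    stop_validation("visit must be a non-negative integer")
  }
  if (any(!is.finite(meta$age_years) | meta$age_years <= 0)) {
    stop_validation("age_years must be positive")
  }
  dup <- duplicated(meta[, c("participant_id", "visit")])
  if (any(dup)) {
    stop_validation(
      "duplicate (participant_id, visit): %s",
      paste(meta$participant_id[dup][1], meta$visit[dup][1])
    )
  }
  baseline <- tapply(meta$visit, meta$participant_id, min)
  if (any(baseline != 0L)) {
    stop_validation(
      "participant %s has no visit-0 record", names(baseline)[baseline != 0L][1]
    )
  }

  # default CDR: 0 for CTR/AMC rows that omit it
  meta$cdr <- suppressWarnings(as.numeric(meta$cdr))
  meta$cdr[is.na(meta$cdr) & meta$group %in% c("CTR", "AMC")] <- 0
  if (any(is.na(meta$cdr))) {
    stop_validation("SMC rows must supply a CDR value")
  }
  if (!all(meta$cdr %in% c(0, 0.5, 1, 2, 3))) {
    stop_validation("cdr must be one of 0, 0.5, 1, 2, 3")
  }
  bad_ctr <- meta$group %in% c("CTR", "AMC") & meta$cdr != 0
  if (any(bad_ctr)) {
    stop_validation(
      "participant %s: group %s requires CDR = 0 (got %g)",
      meta$participant_id[bad_ctr][1], meta$group[bad_ctr][1], meta$cdr[bad_ctr][1]
    )
  }
  bad_smc <- meta$group == "SMC" & meta$cdr < 0.5
  if (any(bad_smc)) {
    stop_validation(
      "participant %s: group SMC requires CDR >= 0.5",
      meta$participant_id[bad_smc][1]
    )
  }

  # derived: symptomatic subgroup from CDR
  derived_sub <- ifelse(
    meta$group != "SMC", "none", ifelse(meta$cdr == 0.5, "SMC_MCI", "SMC_AD")
  )
  given <- !is.na(meta$smc_subgroup)
  if (any(given & meta$smc_subgroup != derived_sub)) {
    i <- which(given & meta$smc_subgroup != derived_sub)[1]
    stop_validation(
      "participant %s: smc_subgroup %s inconsistent with CDR %g",
      meta$participant_id[i], meta$smc_subgroup[i], meta$cdr[i]
    )
  }
  meta$smc_subgroup <- derived_sub

  # derived: APOE e4 carriership from genotype
  known_gt <- c("2/2", "2/3", "2/4", "3/3", "3/4", "4/4")
  gt <- as.character(meta$apoe_genotype)
  gt[gt %in% c("", "NA")] <- NA
  if (any(!is.na(gt) & !gt %in% known_gt)) {
    stop_validation(
      "unknown APOE genotype: %s", setdiff(unique(gt), c(known_gt, NA))[1]
    )
  }
  meta$apoe_genotype <- gt
  derived_e4 <- grepl("4", gt)
  derived_e4[is.na(gt)] <- NA
  given_e4 <- !is.na(meta$apoe_e4_carrier)
  meta$apoe_e4_carrier <- as.logical(meta$apoe_e4_carrier)
  if (any(given_e4 & !is.na(derived_e4) & meta$apoe_e4_carrier != derived_e4)) {
    stop_validation("apoe_e4_carrier inconsistent with apoe_genotype")
  }
  meta$apoe_e4_carrier <- ifelse(is.na(derived_e4), meta$apoe_e4_carrier, derived_e4)

  gene <- as.character(meta$mutation_gene)
  gene[is.na(gene) | gene == ""] <- "none"
  if (!all(gene %in% c("none", "PSEN1", "PSEN2", "APP"))) {
    stop_validation("mutation_gene must be one of none, PSEN1, PSEN2, APP")
  }
  if (any(gene == "none" & meta$group != "CTR")) {
    stop_validation("mutation carriers (AMC/SMC) must carry a mutation gene")
  }
  meta$mutation_gene <- gene

  cohort <- as.character(meta$cohort)
  cohort[is.na(cohort) | cohort == ""] <- "barcelona_like"
  if (!all(cohort %in% c("barcelona_like", "dian_like"))) {
    stop_validation("cohort must be 'barcelona_like' or 'dian_like'")
  }
  meta$cohort <- cohort

  for (col in c("parent_onset_age_years", "eyo_years", "mmse", "csf_nfl_pg_ml",
                "plasma_nfl_pg_ml", "hippocampal_volume_mm3", "age_years")) {
    meta[[col]] <- suppressWarnings(as.numeric(meta[[col]]))
  }
  if (any(!is.na(meta$mmse) & (meta$mmse < 0 | meta$mmse > 30))) {
    stop_validation("mmse must lie in [0, 30]")
  }
  for (col in c("csf_nfl_pg_ml", "plasma_nfl_pg_ml", "hippocampal_volume_mm3",
                "parent_onset_age_years")) {
    if (any(!is.na(meta[[col]]) & meta[[col]] <= 0)) {
      stop_validation("%s must be positive where present", col)
    }
  }
  # fill EYO from parental onset where possible
  need <- is.na(meta$eyo_years) & !is.na(meta$parent_onset_age_years)
  meta$eyo_years[need] <-
    compute_eyo(meta$age_years[need], meta$parent_onset_age_years[need])
  meta
}

#' Write a metadata table
#'
#' @param meta Metadata tibble.
#' @param path Output CSV path.
#' @export
write_metadata <- function(meta, path) {
  readr::write_csv(meta, path, progress = FALSE, na = "")
  invisible(path)
}

#' Estimated years from symptom onset
#'
#' EYO is the participant's age at visit minus the age at which their affected
#' parent first developed symptoms; negative values are years before the
#' expected onset.
#'
#' @param age_years Participant age at visit (years, positive).
#' @param parent_onset_age_years Affected parent's symptom-onset age (years,
#'   positive).
#' @return `age_years - parent_onset_age_years`, vectorised.
#' @export
#' @examples
#' compute_eyo(45, 48) # -3: three years before expected onset
compute_eyo <- function(age_years, parent_onset_age_years) {
  if (any(!is.finite(age_years)) || any(age_years <= 0) ||
      any(!is.finite(parent_onset_age_years)) || any(parent_onset_age_years <= 0)) {
    stop_domain("ages must be positive and finite")
  }
  age_years - parent_onset_age_years
}

#' Assemble a validated cohort object
#'
#' @param metadata Metadata tibble (see [read_metadata()]).
#' @param thickness Long thickness tibble (see [read_thickness()]).
#' @return A list of class `cohort_table` with elements `metadata` and
#'   `thickness`; every metadata row has exactly one left and one right
#'   34-region profile.
#' @export
cohort_table <- function(metadata, thickness) {
  metadata <- validate_metadata(metadata)
  validate_thickness(thickness)
  key_m <- paste(metadata$participant_id, metadata$visit)
  key_t <- unique(paste(thickness$participant_id, thickness$visit))
  if (!setequal(key_m, key_t)) {
    stop_validation(
      "metadata and thickness tables cover different participant-visits (e.g. %s)",
      c(setdiff(key_m, key_t), setdiff(key_t, key_m))[1]
    )
  }
  structure(list(metadata = metadata, thickness = thickness),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "<cohort_table> %d participants, %d participant-visits, %d thickness rows\n",
    length(unique(x$metadata$participant_id)), nrow(x$metadata), nrow(x$thickness)
  ))
  invisible(x)
}

#' Build the merged analysis table
#'
#' Computes CAI for every participant-visit and appends it to the metadata:
#' the single flat table every downstream analysis consumes.
#'
#' @param cohort A [cohort_table()].
#' @param config A [cai_config()].
#' @return Tibble: one row per participant-visit, metadata columns plus `cai`.
#' @export
build_analysis_table <- function(cohort, config = cai_config()) {
  stopifnot(inherits(cohort, "cohort_table"))
  cai <- compute_cai_table(cohort$thickness, config)
  dplyr::left_join(cohort$metadata, cai, by = c("participant_id", "visit"))
}
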