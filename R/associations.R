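#' Correlate two variables
#'
#' Spearman (average ranks for ties, then the Pearson formula on ranks) or
#' Pearson correlation after pairwise deletion of missing values, with the
#' p-value from the t approximation on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"spearman"` or `"pearson"`.
#' @param variable,subgroup Labels carried into the result.
#' @return A one-row tibble: method, variable, subgroup, r, p, n, flag
#'   (`"ok"`, `"constant_input"` or `"insufficient_n"`; r and p are `NA` when
#'   flagged).
#' @export
#' @examples
#' correlate(1:3, c(10, 20, 30), "spearman")$r # 1
correlate <- function(x, y, method = c("spearman", "pearson"),
                      variable = "y", subgroup = "all") {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_contract("`x` and `y` lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  out <- tibble::tibble(method = method, variable = variable,
                        subgroup = subgroup, r = NA_real_, p = NA_real_,
                        n = n, flag = "ok")
  if (n < 3L) {
    out$flag <- "insufficient_n"
    return(out)
  }
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    out$flag <- "constant_input"
    return(out)
  }
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  r <- stats::cor(x, y)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(tval), df = n - 2)
  out$r <- r
  out$p <- p
  out
}

#' Baseline association battery: CAI against clinical variables
#'
#' For each requested subgroup, correlates baseline CAI with age, EYO, MMSE
#' and NfL (CSF and plasma), using Spearman for small single-centre cohorts
#' and Pearson for large ones. Only visit-0 rows enter; missing biomarker
#' values are dropped pairwise and the remaining n is recorded.
#'
#' @param analysis Analysis table (metadata + `cai`).
#' @param subgroups Named list mapping a subgroup label to a filter over the
#'   baseline table; the default follows the analysis plan: mutation carriers
#'   combined, SMC, and — for `dian_like` tables — AMC, SMC_MCI and SMC_AD.
#' @param variables Analysis-table columns to correlate with CAI.
#' @param method `"spearman"`, `"pearson"`, or `NULL` to pick by the table's
#'   `cohort` field (Spearman for `barcelona_like`, Pearson for `dian_like`).
#' @return Tibble of [correlate()] rows, one per (subgroup, variable).
#' @export
association_battery <- function(analysis,
                                subgroups = NULL,
                                variables = c("age_years", "eyo_years", "mmse",
                                              "csf_nfl_pg_ml", "plasma_nfl_pg_ml"),
                                method = NULL) {
  base <- analysis[analysis$visit == 0L, ]
  template <- if (nrow(base) > 0 && "cohort" %in% names(base)) {
    base$cohort[1]
  } else {
    "barcelona_like"
  }
  if (is.null(method)) {
    method <- if (template == "dian_like") "pearson" else "spearman"
  }
  if (is.null(subgroups)) {
    subgroups <- list(
      mutation_carriers = base$group %in% c("AMC", "SMC"),
      SMC = base$group == "SMC"
    )
    if (template == "dian_like") {
      subgroups$AMC <- base$group == "AMC"
      subgroups$SMC_MCI <- base$smc_subgroup == "SMC_MCI"
      subgroups$SMC_AD <- base$smc_subgroup == "SMC_AD"
    }
  }
  res <- list()
  for (sg in names(subgroups)) {
    sub <- base[subgroups[[sg]], ]
    for (v in variables) {
      res[[paste(sg, v)]] <- correlate(sub$cai, sub[[v]], method,
                                       variable = v, subgroup = sg)
    }
  }
  dplyr::bind_rows(res)
}
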