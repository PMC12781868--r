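#' Configuration for the cortical asymmetry index
#'
#' The CAI compares the left and right hemispheres' distributions of regional
#' mean cortical thickness. The distributions are estimated from the 34
#' Desikan-Killiany regional means per hemisphere, either by an epsilon-
#' smoothed histogram (default) or by a Gaussian kernel density evaluated on a
#' regular grid, over a common support shared by both hemispheres.
#'
#' @param estimator `"histogram"` (default) or `"gaussian_kde"`.
#' @param n_bins Number of equal-width histogram bins, or grid size for the
#'   KDE. Default 16.
#' @param support_policy `"pooled_min_max"` (default): the support is the
#'   participant's pooled left+right thickness range, padded by half a bin
#'   width on each side, making the index purely within-individual.
#'   `"fixed_range"`: use `fixed_range_mm`, e.g. for cross-cohort
#'   standardisation.
#' @param fixed_range_mm Length-2 numeric, lower < upper, in mm. Only used
#'   when `support_policy = "fixed_range"`.
#' @param smoothing_epsilon Small positive mass added to every bin before
#'   renormalisation, so the divergence is finite on empty bins. Default 1e-6.
#'
#' @return A list of class `cai_config`.
#' @export
#' @examples
#' cfg <- cai_config()
#' left <- setNames(rnorm(34, 2.5, 0.25), dk_regions)
#' compute_cai(left, left, cfg) # identical hemispheres -> 0
cai_config <- function(estimator = c("histogram", "gaussian_kde"),
                       n_bins = 16L,
                       support_policy = c("pooled_min_max", "fixed_range"),
                       fixed_range_mm = c(1, 4),
                       smoothing_epsilon = 1e-6) {
  estimator <- match.arg(estimator)
  support_policy <- match.arg(support_policy)
  if (!is_scalar_number(n_bins) || n_bins < 2) {
    stop_validation("`n_bins` must be a single number >= 2, got %s", format(n_bins)[1])
  }
  if (!is_scalar_number(smoothing_epsilon) || smoothing_epsilon <= 0) {
    stop_validation("`smoothing_epsilon` must be a single positive number")
  }
  if (length(fixed_range_mm) != 2L || !all(is.finite(fixed_range_mm)) ||
      fixed_range_mm[1] >= fixed_range_mm[2]) {
    stop_validation("`fixed_range_mm` must be two finite numbers with lower < upper")
  }
  structure(
    list(
      estimator = estimator,
      n_bins = as.integer(n_bins),
      support_policy = support_policy,
      fixed_range_mm = as.numeric(fixed_range_mm),
      smoothing_epsilon = smoothing_epsilon,
      log_base = 2
    ),
    class = "cai_config"
  )
}

#' Estimate a discrete thickness distribution for one hemisphere
#'
#' @param values Numeric vector of regional mean thicknesses (mm), all finite.
#' @param config A [cai_config()].
#' @param support Length-2 numeric: the common support (mm) on which both
#'   hemispheres' distributions are discretised. Must cover all `values`.
#'
#' @return A list of class `discrete_distribution` with `bin_edges` (length
#'   `n_bins + 1`) and `mass` (length `n_bins`, sums to 1).
#' @export
estimate_density <- function(values, config = cai_config(), support) {
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop_domain("thickness values must all be finite numbers")
  }
  if (length(support) != 2L || support[1] >= support[2]) {
    stop_domain("`support` must be an increasing pair of numbers")
  }
  if (any(values < support[1]) || any(values > support[2])) {
    stop_domain(
      "thickness value outside the density support [%g, %g]",
      support[1], support[2]
    )
  }
  k <- config$n_bins
  edges <- seq(support[1], support[2], length.out = k + 1L)

  if (config$estimator == "histogram") {
    # findInterval puts a value equal to the upper edge into bin k.
    idx <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
    mass <- tabulate(idx, nbins = k) / length(values)
    mass <- mass + config$smoothing_epsilon
    mass <- mass / sum(mass)
  } else {
    centers <- (edges[-1] + edges[-(k + 1L)]) / 2
    # Silverman's rule on the pooled-support sample; floor guards constants.
    bw <- stats::bw.nrd0(values)
    if (!is.finite(bw) || bw <= 0) bw <- diff(support) / k
    dens <- vapply(centers, function(x) mean(dnorm(x, mean = values, sd = bw)),
                   numeric(1))
    mass <- dens + config$smoothing_epsilon
    mass <- mass / sum(mass)
  }
  structure(list(bin_edges = edges, mass = mass), class = "discrete_distribution")
}

shannon_entropy_bits <- function(p) {
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Jensen-Shannon distance between two discrete distributions
#'
#' Computes `sqrt(H(m) - (H(p) + H(q)) / 2)` with `m` the pointwise average of
#' the two mass vectors and `H` the Shannon entropy in bits. With base-2
#' logarithms the result is a metric bounded in \[0, 1\]; 0 log 0 is taken
#' as 0.
#'
#' @param p,q `discrete_distribution` objects sharing identical bin edges, or
#'   bare probability vectors of equal length.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' jensen_shannon_distance(c(1, 0), c(0, 1)) # disjoint supports -> 1
jensen_shannon_distance <- function(p, q) {
  pm <- if (inherits(p, "discrete_distribution")) p$mass else p
  qm <- if (inherits(q, "discrete_distribution")) q$mass else q
  if (inherits(p, "discrete_distribution") && inherits(q, "discrete_distribution")) {
    if (length(p$bin_edges) != length(q$bin_edges) ||
        max(abs(p$bin_edges - q$bin_edges)) > 1e-9) {
      stop_contract("distributions must share identical bin edges")
    }
  }
  if (length(pm) != length(qm)) {
    stop_contract("mass vectors must have equal length")
  }
  if (any(pm < 0) || any(qm < 0)) stop_domain("masses must be non-negative")
  if (abs(sum(pm) - 1) > 1e-8 || abs(sum(qm) - 1) > 1e-8) {
    stop_domain("masses must each sum to 1")
  }
  m <- (pm + qm) / 2
  jsd2 <- shannon_entropy_bits(m) -
    (shannon_entropy_bits(pm) + shannon_entropy_bits(qm)) / 2
  # numerical noise can push the divergence epsilon-negative or past 1
  sqrt(min(max(jsd2, 0), 1))
}

#' Cortical asymmetry index for one participant-visit
#'
#' CAI is the Jensen-Shannon distance between the left and right hemispheres'
#' estimated thickness distributions: a dimensionless scalar in \[0, 1\],
#' higher meaning a more asymmetric brain. Under the default
#' `pooled_min_max` policy the support is the pooled range of both
#' hemispheres' values, padded by half a bin width each side.
#'
#' @param left,right Named numeric vectors of 34 regional mean thicknesses
#'   (mm), same region order. Names, when present, must match between
#'   hemispheres; region identity does not otherwise enter the index.
#' @param config A [cai_config()].
#' @return The CAI value (numeric scalar in \[0, 1\]).
#' @export
compute_cai <- function(left, right, config = cai_config()) {
  if (length(left) != length(right)) {
    stop_contract("left and right profiles must have the same length")
  }
  if (!is.null(names(left)) && !is.null(names(right)) &&
      !identical(names(left), names(right))) {
    stop_contract("left and right profiles must share the same region order")
  }
  if (!all(is.finite(left)) || !all(is.finite(right)) ||
      any(left <= 0) || any(right <= 0)) {
    stop_domain("thickness values must be positive and finite")
  }
  support <- cai_support(left, right, config)
  dl <- estimate_density(left, config, support)
  dr <- estimate_density(right, config, support)
  jensen_shannon_distance(dl, dr)
}

cai_support <- function(left, right, config) {
  if (config$support_policy == "fixed_range") {
    return(config$fixed_range_mm)
  }
  pooled <- range(c(left, right))
  width <- diff(pooled)
  if (width == 0) {
    # degenerate pooled range (all 68 values identical): any symmetric
    # support gives identical distributions and CAI = 0
    return(pooled + c(-0.5, 0.5))
  }
  pad <- width / config$n_bins / 2
  pooled + c(-pad, pad)
}

#' Compute CAI for every participant-visit of a long thickness table
#'
#' @param thickness Long thickness table as returned by [read_thickness()] or
#'   found in a cohort's `$thickness`: columns `participant_id`, `visit`,
#'   `hemisphere`, `region`, `thickness_mm`.
#' @param config A [cai_config()].
#' @return Tibble with columns `participant_id`, `visit`, `cai`.
#' @export
compute_cai_table <- function(thickness, config = cai_config()) {
  validate_thickness(thickness)
  # after validation each participant-visit has exactly 34 left + 34 right
  # rows; sorting by (id, visit, hemisphere, region) aligns the hemispheres
  ord <- order(thickness$participant_id, thickness$visit,
               thickness$hemisphere, thickness$region)
  th <- thickness[ord, ]
  m <- matrix(th$thickness_mm, nrow = 68L)
  keys <- th[seq(1, nrow(th), by = 68L), c("participant_id", "visit")]
  tibble::tibble(
    participant_id = keys$participant_id,
    visit = keys$visit,
    cai = vapply(seq_len(ncol(m)), function(j) {
      compute_cai(m[1:34, j], m[35:68, j], config)
    }, numeric(1))
  )
}
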