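#' @importFrom rlang %||% abort warn hash
#' @importFrom stats anova as.formula coef fisher.test kruskal.test lm
#'   model.matrix p.adjust pnorm predict pt qnorm quantile rbinom rlnorm rnorm
#'   runif sd setNames var cor.test aov residuals fitted dnorm
#' @importFrom utils head
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a base seed, kept below 2^31.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(
    cohort = 11L, thickness = 23L, biomarker = 37L, visits = 41L,
    permutation = 53L, replicate = 67L, gam = 79L, pipeline = 97L
  )
  off <- offsets[[stream]] %||% 7L
  as.integer((as.numeric(seed) * 1009 + off * 101) %% 2147483647)
}

stop_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "cortasym_validation_error")
}

stop_contract <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "cortasym_contract_error")
}

stop_domain <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "cortasym_domain_error")
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
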