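# Internal helpers shared across modules.

#' Derive a stage-specific seed from a global seed
#'
#' A single pipeline seed is fanned out to stages through a counter-based
#' linear-congruential mix, so any stage can be re-run on its own with stable
#' randomness. The result is always a positive 32-bit integer.
#'
#' @param seed Integer global seed.
#' @param key Character stage label (e.g. `"population"`, `"network"`).
#' @param counter Optional non-negative integer for repeated draws under the
#'   same key (e.g. one seed per stratum).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' fan_seed(1, "population")
#' fan_seed(1, "network", counter = 3)
fan_seed <- function(seed, key, counter = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.numeric(seed) %% m)
  x <- (x * 48271 + 11) %% m
  for (ch in utf8ToInt(key)) x <- (x * 69621 + ch) %% m
  x <- (x * 48271 + as.numeric(counter)) %% m
  as.integer(x %% (m - 1) + 1)
}

# assert a matrix is symmetric positive definite; returns its Cholesky factor
chol_pd <- function(sigma, what = "covariance") {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    abort(sprintf("%s matrix is not positive definite", what),
          class = "efnet_config_error")
  }
  ch
}

# multivariate normal log-density for a data matrix (rows = observations)
mvn_loglik <- function(x, mu, sigma) {
  x <- as.matrix(x)
  p <- ncol(x)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mu)
  -0.5 * nrow(x) * (p * log(2 * pi) + 2 * sum(log(diag(ch)))) -
    0.5 * sum(z^2)
}

#' The eight EF metric columns, in canonical order
#'
#' Column names of the task metrics of interest, in the fixed order used by
#' every network and factor model in the package.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' ef_metric_columns()
ef_metric_columns <- function() {
  c("forward_span", "backward_span",
    "sustained_rt_sd", "impulsive_dprime", "tap_trace_dprime",
    "stroop_rcs", "flanker_rcs", "boxed_mean_rt")
}

ef_cohorts <- function() c("G34", "G56", "G78")

# component membership of the 8 EF metrics (working memory, context
# monitoring, interference resolution)
ef_component_map <- function() {
  c(forward_span = "WM", backward_span = "WM",
    sustained_rt_sd = "CM", impulsive_dprime = "CM", tap_trace_dprime = "CM",
    stroop_rcs = "IR", flanker_rcs = "IR", boxed_mean_rt = "IR")
}

`%||%` <- rlang::`%||%`
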