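#' Build a generator configuration
#'
#' Assembles and validates every tunable of the synthetic accelerated
#' longitudinal design: cohort sizes and entry-age distributions, the latent
#' ability model (a Common-EF general factor plus working-memory,
#' context-monitoring and interference-resolution components), per-month
#' growth, the adaptive staircase settings, metric-level factor structure per
#' cohort and timepoint, and missingness rates.
#'
#' The default design emulates a two-year, four-timepoint study of three
#' school cohorts (grades 3-4, 5-6, 7-8) assessed each fall and spring with
#' an adaptive EF battery of a basic response-time task plus eight EF tasks.
#'
#' @param n_per_cohort Named integer vector of students per cohort
#'   (`G34`, `G56`, `G78`).
#' @param seed Integer seed; every generator draw is deterministic given it.
#' @param n_timepoints Number of assessment waves (default 4).
#' @param session_gap_months Months between consecutive waves (default 6,
#'   i.e. fall/spring of two school years).
#' @param age_mean_months,age_sd_months Named vectors of entry-age mean/SD in
#'   months per cohort.
#' @param growth_per_month Named vector: per-month gain of every latent
#'   ability, in SD units, per cohort. Younger cohorts grow faster by
#'   default, which is the age-by-time interaction.
#' @param ability_corr 4x4 correlation matrix of the latent abilities
#'   `(g, wm, cm, ir)`; the general factor is orthogonal to the specifics by
#'   default.
#' @param gender_effect Additive shift (SD units) of the specific abilities
#'   for students coded female.
#' @param colorblind_rate Probability a student screens red-green colorblind.
#' @param n_schools Number of school clusters.
#' @param speed_base_ms,speed_age_slope,speed_sd_log Latent processing-speed
#'   model: median RT scale in ms at age 120 months, proportional change per
#'   month of age, and lognormal dispersion.
#' @param window_init_ms,step_down_ms,step_up_ms,window_floor_ms Adaptive
#'   response-window staircase: initial deadline, shrink on correct-in-window
#'   feedback, growth otherwise, and the positive floor. The long-run
#'   fraction of correct feedback among responses is
#'   `step_up / (step_up + step_down)`, 0.75 by default.
#' @param span_start,span_max,span_fail_limit,span_min_trials Span
#'   staircase: starting length, cap, the number of failures at one length
#'   that ends a block, and the minimum attempts administered (further
#'   blocks restart at the base length until it is met).
#' @param loading_general,loading_specific Standardized loadings of each
#'   metric on the Common-EF general factor and on its specific component.
#' @param factor_corr_specific Correlation between specific components.
#' @param brt_cor Correlation of the standardized BRT column with the
#'   Common-EF factor.
#' @param structure Named list per cohort giving `k` (number of specific
#'   components, 1-3) and, for `k = 2`, `merge`: a length-`n_timepoints`
#'   character vector saying which pair of components is collapsed at each
#'   wave (`"CM+IR"`, `"WM+CM"` or `"WM+IR"`).
#' @param structural_drift Named vector: SD of per-stratum loading
#'   perturbation per cohort, controlling how stable a cohort's network is
#'   across timepoints.
#' @param missing_session_rate,missing_task_rate MCAR masking rates for whole
#'   sessions and individual task blocks.
#' @param trials List of per-task trial counts overriding the battery
#'   defaults (see [task_battery()]).
#' @return An object of class `ef_config` (a validated named list).
#' @export
#' @examples
#' cfg <- ef_config(n_per_cohort = c(G34 = 50, G56 = 50, G78 = 50), seed = 1)
#' cfg$cohorts
ef_config <- function(n_per_cohort = c(G34 = 280, G56 = 260, G78 = 450),
                      seed = 1L,
                      n_timepoints = 4L,
                      session_gap_months = 6,
                      age_mean_months = c(G34 = 96.8, G56 = 119.8, G78 = 142.8),
                      age_sd_months = c(G34 = 4.2, G56 = 4.9, G78 = 5.6),
                      growth_per_month = c(G34 = 0.030, G56 = 0.020, G78 = 0.015),
                      ability_corr = default_ability_corr(),
                      gender_effect = 0.10,
                      colorblind_rate = 0.02,
                      n_schools = 9L,
                      speed_base_ms = 450,
                      speed_age_slope = 0.004,
                      speed_sd_log = 0.15,
                      window_init_ms = 1200,
                      step_down_ms = 10,
                      step_up_ms = 30,
                      window_floor_ms = 200,
                      span_start = 2L,
                      span_max = 12L,
                      span_fail_limit = 2L,
                      span_min_trials = 6L,
                      loading_general = 0.45,
                      loading_specific = 0.60,
                      factor_corr_specific = 0.25,
                      brt_cor = 0.40,
                      structure = default_structure(n_timepoints),
                      structural_drift = c(G34 = 0.15, G56 = 0.05, G78 = 0.03),
                      missing_session_rate = 0.10,
                      missing_task_rate = 0.05,
                      trials = list()) {
  cohorts <- ef_cohorts()
  n_per_cohort <- n_per_cohort[cohorts]
  names(n_per_cohort) <- cohorts
  n_per_cohort[is.na(n_per_cohort)] <- 0L
  if (any(n_per_cohort < 0)) {
    abort("n_per_cohort must be non-negative", class = "efnet_config_error")
  }
  rates <- c(missing_session_rate, missing_task_rate, colorblind_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("rates must lie in [0, 1]", class = "efnet_config_error")
  }
  if (window_floor_ms <= 0 || window_init_ms < window_floor_ms) {
    abort("window floor must be positive and no larger than the initial window",
          class = "efnet_config_error")
  }
  if (step_down_ms <= 0 || step_up_ms <= 0) {
    abort("staircase steps must be positive", class = "efnet_config_error")
  }
  stopifnot(is.matrix(ability_corr), all(dim(ability_corr) == 4L))
  chol_pd(ability_corr, "ability correlation")
  if (loading_general^2 + loading_specific^2 >= 1) {
    abort("general and specific loadings imply non-positive uniqueness",
          class = "efnet_config_error")
  }
  for (co in cohorts) {
    st <- structure[[co]]
    if (is.null(st) || !st$k %in% 1:3) {
      abort(sprintf("structure for cohort %s must give k in 1..3", co),
            class = "efnet_config_error")
    }
    if (st$k == 2L && length(st$merge) != n_timepoints) {
      abort("k = 2 structures need one merge label per timepoint",
            class = "efnet_config_error")
    }
  }
  cfg <- list(
    cohorts = tibble::tibble(
      cohort = cohorts,
      n = as.integer(n_per_cohort),
      age_mean_months = unname(age_mean_months[cohorts]),
      age_sd_months = unname(age_sd_months[cohorts]),
      growth_per_month = unname(growth_per_month[cohorts]),
      structural_drift = unname(structural_drift[cohorts])
    ),
    seed = as.integer(seed),
    n_timepoints = as.integer(n_timepoints),
    session_gap_months = session_gap_months,
    ability_corr = ability_corr,
    gender_effect = gender_effect,
    colorblind_rate = colorblind_rate,
    n_schools = as.integer(n_schools),
    speed = list(base_ms = speed_base_ms, age_slope = speed_age_slope,
                 sd_log = speed_sd_log),
    staircase = list(window_init_ms = window_init_ms,
                     step_down_ms = step_down_ms,
                     step_up_ms = step_up_ms,
                     floor_ms = window_floor_ms),
    span = list(start = span_start, max = span_max,
                fail_limit = span_fail_limit, min_trials = span_min_trials),
    loadings = list(general = loading_general, specific = loading_specific,
                    factor_corr = factor_corr_specific, brt_cor = brt_cor),
    structure = structure,
    missing_session_rate = missing_session_rate,
    missing_task_rate = missing_task_rate,
    trials = trials
  )
  structure(cfg, class = "ef_config")
}

#' @export
print.ef_config <- function(x, ...) {
  cat("<ef_config>\n")
  cat("  cohorts:", paste(sprintf("%s n=%d", x$cohorts$cohort, x$cohorts$n),
                          collapse = ", "), "\n")
  cat("  timepoints:", x$n_timepoints,
      sprintf("(gap %.0f months)", x$session_gap_months), "\n")
  eq <- x$staircase$step_up_ms / (x$staircase$step_up_ms + x$staircase$step_down_ms)
  cat(sprintf("  staircase: init %.0f ms, -%.0f/+%.0f ms (target %.0f%% correct feedback)\n",
              x$staircase$window_init_ms, x$staircase$step_down_ms,
              x$staircase$step_up_ms, 100 * eq))
  ks <- vapply(ef_cohorts(), function(co) x$structure[[co]]$k, integer(1))
  cat("  metric structure k:", paste(sprintf("%s=%d", names(ks), ks),
                                     collapse = ", "), "\n")
  invisible(x)
}

#' Default latent ability correlation matrix
#'
#' Common EF (`g`) is orthogonal to the three specific components, which
#' correlate 0.25 among themselves.
#'
#' @return A 4x4 correlation matrix with dimnames `(g, wm, cm, ir)`.
#' @export
default_ability_corr <- function() {
  nm <- c("g", "wm", "cm", "ir")
  m <- diag(4)
  m[2:4, 2:4] <- 0.25
  diag(m) <- 1
  dimnames(m) <- list(nm, nm)
  m
}

#' Default per-cohort factor structure
#'
#' The youngest cohort is generated with two distinguishable components (one
#' theorized pair collapsed, a different pair at each wave), the two older
#' cohorts with the full three-component structure at every wave — the
#' developmental differentiation pattern the pipeline is designed to detect.
#'
#' @param n_timepoints Number of waves the merge schedule must cover.
#' @return Named list with entries `G34`, `G56`, `G78`.
#' @export
default_structure <- function(n_timepoints = 4L) {
  merges <- rep(c("CM+IR", "WM+CM", "WM+IR", "WM+IR"),
                length.out = n_timepoints)
  list(
    G34 = list(k = 2L, merge = merges),
    G56 = list(k = 3L),
    G78 = list(k = 3L)
  )
}

#' Read / write a generator configuration as YAML
#'
#' Only scalar and vector fields are serialized; matrices are stored as row
#' lists. `read_ef_config()` rebuilds and revalidates through [ef_config()].
#'
#' @param config An `ef_config`.
#' @param path File path.
#' @return `write_ef_config()` returns `path` invisibly; `read_ef_config()`
#'   returns an `ef_config`.
#' @export
write_ef_config <- function(config, path) {
  stopifnot(inherits(config, "ef_config"))
  co <- config$cohorts
  out <- list(
    n_per_cohort = as.list(setNames(co$n, co$cohort)),
    seed = config$seed,
    n_timepoints = config$n_timepoints,
    session_gap_months = config$session_gap_months,
    age_mean_months = as.list(setNames(co$age_mean_months, co$cohort)),
    age_sd_months = as.list(setNames(co$age_sd_months, co$cohort)),
    growth_per_month = as.list(setNames(co$growth_per_month, co$cohort)),
    structural_drift = as.list(setNames(co$structural_drift, co$cohort)),
    gender_effect = config$gender_effect,
    colorblind_rate = config$colorblind_rate,
    n_schools = config$n_schools,
    speed = config$speed,
    staircase = config$staircase,
    span = config$span,
    loadings = config$loadings,
    structure = config$structure,
    missing_session_rate = config$missing_session_rate,
    missing_task_rate = config$missing_task_rate,
    ability_corr = apply(config$ability_corr, 1, as.list)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_ef_config
#' @export
read_ef_config <- function(path) {
  y <- yaml::read_yaml(path)
  ab <- diag(4)
  if (!is.null(y$ability_corr)) {
    ab <- do.call(rbind, lapply(y$ability_corr, function(r) unlist(r, use.names = FALSE)))
    dimnames(ab) <- dimnames(default_ability_corr())
  }
  structure_y <- lapply(y$structure, function(s) {
    s$k <- as.integer(s$k)
    s
  })
  ef_config(
    n_per_cohort = unlist(y$n_per_cohort),
    seed = y$seed,
    n_timepoints = y$n_timepoints,
    session_gap_months = y$session_gap_months,
    age_mean_months = unlist(y$age_mean_months),
    age_sd_months = unlist(y$age_sd_months),
    growth_per_month = unlist(y$growth_per_month),
    ability_corr = ab,
    gender_effect = y$gender_effect,
    colorblind_rate = y$colorblind_rate,
    n_schools = y$n_schools,
    speed_base_ms = y$speed$base_ms,
    speed_age_slope = y$speed$age_slope,
    speed_sd_log = y$speed$sd_log,
    window_init_ms = y$staircase$window_init_ms,
    step_down_ms = y$staircase$step_down_ms,
    step_up_ms = y$staircase$step_up_ms,
    window_floor_ms = y$staircase$floor_ms,
    span_start = y$span$start,
    span_max = y$span$max,
    span_fail_limit = y$span$fail_limit,
    span_min_trials = y$span$min_trials,
    loading_general = y$loadings$general,
    loading_specific = y$loadings$specific,
    factor_corr_specific = y$loadings$factor_corr,
    brt_cor = y$loadings$brt_cor,
    structure = structure_y,
    structural_drift = unlist(y$structural_drift),
    missing_session_rate = y$missing_session_rate,
    missing_task_rate = y$missing_task_rate
  )
}
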