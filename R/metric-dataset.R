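# Metric-level generator: draws standardized task metrics directly from the
# factor model Lambda Phi Lambda' + Psi, bypassing trial simulation. This is
# the ground-truth input for the network and CFA stages.

# Build the loading matrix for one cohort x timepoint. First column is the
# Common-EF general factor (orthogonal to specifics); remaining columns are
# the k specific components. Unit metric variances: uniqueness by difference.
stratum_loadings <- function(config, cohort, timepoint) {
  st <- config$structure[[cohort]]
  ld <- config$loadings
  comp <- ef_component_map()
  members <- split(names(comp), comp)[c("WM", "CM", "IR")]
  groups <- switch(as.character(st$k),
    "1" = list(ALL = unlist(members, use.names = FALSE)),
    "2" = {
      merge <- st$merge[[timepoint]]
      pair <- strsplit(merge, "+", fixed = TRUE)[[1]]
      apart <- setdiff(c("WM", "CM", "IR"), pair)
      out <- list(unlist(members[pair], use.names = FALSE),
                  members[[apart]])
      names(out) <- c(paste(pair, collapse = "_"), apart)
      out
    },
    "3" = members
  )
  k <- length(groups)
  tasks <- ef_metric_columns()
  lambda <- matrix(0, length(tasks), k + 1L,
                   dimnames = list(tasks, c("gEF", names(groups))))
  lambda[, 1L] <- ld$general
  for (j in seq_along(groups)) {
    lambda[groups[[j]], j + 1L] <- ld$specific
  }
  # per-stratum structural drift perturbs specific loadings, deterministically
  drift <- config$cohorts$structural_drift[config$cohorts$cohort == cohort]
  if (drift > 0) {
    withr::with_seed(fan_seed(config$seed, "drift",
                              counter = 100L * match(cohort, ef_cohorts()) + timepoint), {
      jit <- matrix(rnorm(length(tasks) * k, 0, drift), length(tasks), k)
      cap <- sqrt(0.95 - ld$general^2) # keeps every uniqueness above 0.05
      lam_s <- lambda[, -1L, drop = FALSE]
      pos <- lam_s > 0
      lam_s[pos] <- pmin(cap, pmax(0.1, lam_s[pos] + jit[pos]))
      lambda[, -1L] <- lam_s
    })
  }
  phi <- diag(k + 1L)
  if (k > 1L) {
    phi[-1L, -1L][row(diag(k)) != col(diag(k))] <- ld$factor_corr
  }
  dimnames(phi) <- list(colnames(lambda), colnames(lambda))
  psi <- 1 - rowSums((lambda %*% phi) * lambda)
  if (any(psi <= 0)) {
    abort("implied uniquenesses are not positive; reduce loadings or drift",
          class = "efnet_config_error")
  }
  list(lambda = lambda, phi = phi, psi = psi, groups = groups)
}

#' Implied metric covariance for one cohort x timepoint
#'
#' Returns the population structure the generator draws from:
#' `sigma = lambda %*% phi %*% t(lambda) + diag(psi)` with unit diagonal,
#' together with the planted community assignment of the 8 metrics.
#'
#' @param config An [ef_config()].
#' @param cohort One of `"G34"`, `"G56"`, `"G78"`.
#' @param timepoint Integer wave.
#' @return A list with `sigma`, `lambda`, `phi`, `psi`, and `communities`
#'   (named integer vector over the 8 metric columns).
#' @export
stratum_structure <- function(config, cohort, timepoint) {
  parts <- stratum_loadings(config, cohort, timepoint)
  sigma <- parts$lambda %*% parts$phi %*% t(parts$lambda) + diag(parts$psi)
  chol_pd(sigma, "implied metric covariance")
  communities <- integer(length(ef_metric_columns()))
  names(communities) <- ef_metric_columns()
  for (j in seq_along(parts$groups)) {
    communities[parts$groups[[j]]] <- j - 1L
  }
  list(sigma = sigma, lambda = parts$lambda, phi = parts$phi,
       psi = parts$psi, communities = communities)
}

#' Generate a metric-level dataset with known factor structure
#'
#' Draws `n` rows of the 8 standardized EF metrics from the multivariate
#' normal implied by the stratum's loading structure (Common-EF general
#' factor plus `k` specific components), together with a BRT column
#' correlated with the general factor and rescaled to milliseconds. This is
#' the generator used to benchmark network estimation, community detection
#' and CFA against planted truth.
#'
#' @param config An [ef_config()].
#' @param cohort Cohort label.
#' @param timepoint Integer wave.
#' @param n Rows to draw (default: the cohort's configured size).
#' @param seed Optional seed override.
#' @return A tibble with `student_id`, `cohort`, `timepoint`, `age_months`,
#'   `months_since_first`, `gender`, `school_id`, `brt_mean_rt` and the 8
#'   metric columns. Attribute `"structure"` carries the
#'   [stratum_structure()] ground truth.
#' @export
#' @examples
#' cfg <- ef_config(seed = 7)
#' d <- generate_metric_dataset(cfg, "G78", 1, n = 200)
#' attr(d, "structure")$communities
generate_metric_dataset <- function(config, cohort, timepoint,
                                    n = NULL, seed = NULL) {
  stopifnot(cohort %in% ef_cohorts())
  n <- n %||% config$cohorts$n[config$cohorts$cohort == cohort]
  seed <- seed %||% fan_seed(config$seed, "metrics",
                             counter = 100L * match(cohort, ef_cohorts()) + timepoint)
  truth <- stratum_structure(config, cohort, timepoint)
  crow <- config$cohorts[config$cohorts$cohort == cohort, ]
  months <- (as.integer(timepoint) - 1L) * config$session_gap_months
  withr::with_seed(as.integer(seed), {
    p <- length(truth$psi)
    scores <- MASS::mvrnorm(n, mu = rep(0, ncol(truth$lambda)),
                            Sigma = truth$phi)
    if (n == 1L) scores <- matrix(scores, nrow = 1L)
    metrics <- scores %*% t(truth$lambda) +
      matrix(rnorm(n * p), n, p) %*% diag(sqrt(truth$psi))
    colnames(metrics) <- ef_metric_columns()
    rho <- config$loadings$brt_cor
    brt_std <- rho * scores[, 1L] + sqrt(1 - rho^2) * rnorm(n)
    out <- tibble::tibble(
      student_id = sprintf("%s_t%d_%05d", cohort, as.integer(timepoint),
                           seq_len(n)),
      cohort = cohort,
      timepoint = as.integer(timepoint),
      age_months = rnorm(n, crow$age_mean_months + months, crow$age_sd_months),
      months_since_first = months,
      gender = sample(c("male", "female"), n, replace = TRUE),
      school_id = sprintf("school_%02d",
                          sample.int(config$n_schools, n, replace = TRUE)),
      brt_mean_rt = 400 + 75 * brt_std
    )
    out <- dplyr::bind_cols(out, tibble::as_tibble(metrics))
    attr(out, "structure") <- truth
    out
  })
}

#' Generate metric datasets for every cohort x timepoint stratum
#'
#' @param config An [ef_config()].
#' @param n Optional per-stratum row count override.
#' @return A tibble binding all strata, with a `"structures"` attribute:
#'   a named list (`"G34_t1"`, ...) of [stratum_structure()] truths.
#' @export
generate_metric_study <- function(config, n = NULL) {
  grid <- tidyr::expand_grid(cohort = ef_cohorts(),
                             timepoint = seq_len(config$n_timepoints))
  parts <- purrr::pmap(grid, function(cohort, timepoint) {
    generate_metric_dataset(config, cohort, timepoint, n = n)
  })
  structures <- setNames(purrr::map(parts, attr, "structure"),
                         sprintf("%s_t%d", grid$cohort, grid$timepoint))
  out <- dplyr::bind_rows(parts)
  attr(out, "structures") <- structures
  out
}
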