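#' Simulate a student population
#'
#' Draws one row per student with demographics, entry age, latent processing
#' speed, and the standardized latent abilities `(g, wm, cm, ir)` — the
#' Common-EF general factor and the working-memory, context-monitoring and
#' interference-resolution components — with the configured correlation
#' structure. These latent values are the generative ground truth every later
#' stage is benchmarked against.
#'
#' @param config An [ef_config()].
#' @return A tibble with columns `student_id`, `cohort`, `gender`,
#'   `school_id`, `age_months_at_entry`, `colorblind`, `speed` (latent median
#'   RT scale, ms), abilities `g`, `wm`, `cm`, `ir`, and `growth` (SD units
#'   per month).
#' @export
#' @examples
#' pop <- simulate_population(ef_config(n_per_cohort = c(G34 = 5, G56 = 5, G78 = 5)))
#' pop
simulate_population <- function(config) {
  stopifnot(inherits(config, "ef_config"))
  chol_ab <- chol_pd(config$ability_corr, "ability correlation")
  withr::with_seed(fan_seed(config$seed, "population"), {
    rows <- purrr::pmap(config$cohorts, function(cohort, n, age_mean_months,
                                                 age_sd_months,
                                                 growth_per_month, ...) {
      if (n == 0L) {
        return(NULL)
      }
      abilities <- matrix(rnorm(n * 4L), n, 4L) %*% chol_ab
      colnames(abilities) <- c("g", "wm", "cm", "ir")
      gender <- sample(c("male", "female"), n, replace = TRUE)
      shift <- ifelse(gender == "female", config$gender_effect, 0)
      age <- rnorm(n, age_mean_months, age_sd_months)
      speed <- config$speed$base_ms *
        exp(-config$speed$age_slope * (age - 120) +
              rnorm(n, 0, config$speed$sd_log))
      tibble::tibble(
        student_id = sprintf("%s_%04d", cohort, seq_len(n)),
        cohort = cohort,
        gender = gender,
        school_id = sprintf("school_%02d",
                            sample.int(config$n_schools, n, replace = TRUE)),
        age_months_at_entry = age,
        colorblind = runif(n) < config$colorblind_rate,
        speed = speed,
        g = abilities[, "g"],
        wm = abilities[, "wm"] + shift,
        cm = abilities[, "cm"] + shift,
        ir = abilities[, "ir"] + shift,
        growth = growth_per_month
      )
    })
    dplyr::bind_rows(rows)
  })
}
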