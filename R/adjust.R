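# Adjustment stage: remove basic response speed from every EF metric and
# summarize how much cohort/time still explain of the staircase feedback rate.

#' Residualize EF metrics on basic response time
#'
#' Within each cohort x timepoint stratum, each EF metric column is replaced
#' by the standardized residual (mean 0, SD 1) of its OLS regression on
#' `brt_mean_rt`. Rows missing either the metric or BRT stay `NA`. This
#' produces the speed-adjusted columns the network and factor models
#' consume.
#'
#' @param metric_table Metric tibble (e.g. [build_metric_table()] or
#'   [generate_metric_dataset()] output).
#' @param cohort,timepoint Optional filters; default adjusts every stratum
#'   present.
#' @param min_pairs Minimum complete (metric, BRT) pairs per stratum column
#'   (default 3).
#' @return The metric tibble with EF metric columns replaced by standardized
#'   residuals.
#' @export
residualize_on_brt <- function(metric_table, cohort = NULL, timepoint = NULL,
                               min_pairs = 3L) {
  if (!is.null(cohort)) {
    metric_table <- metric_table[metric_table$cohort %in% cohort, , drop = FALSE]
  }
  if (!is.null(timepoint)) {
    metric_table <- metric_table[metric_table$timepoint %in% timepoint, , drop = FALSE]
  }
  if (!"brt_mean_rt" %in% names(metric_table)) {
    abort("metric table has no brt_mean_rt column", class = "efnet_adjust_error")
  }
  metric_cols <- intersect(ef_metric_columns(), names(metric_table))
  grp <- interaction(metric_table$cohort, metric_table$timepoint, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    brt <- metric_table$brt_mean_rt[idx]
    for (col in metric_cols) {
      y <- metric_table[[col]][idx]
      ok <- !is.na(y) & !is.na(brt)
      if (sum(ok) < min_pairs) {
        abort(sprintf("fewer than %d complete (%s, BRT) pairs in stratum %s",
                      min_pairs, col, g), class = "efnet_adjust_error")
      }
      if (var(brt[ok]) == 0) {
        abort(sprintf("BRT is constant in stratum %s", g),
              class = "efnet_adjust_error")
      }
      res <- residuals(lm(y[ok] ~ brt[ok]))
      s <- sd(res)
      if (s < sqrt(.Machine$double.eps)) {
        abort(sprintf("residuals of %s on BRT are degenerate in stratum %s",
                      col, g), class = "efnet_adjust_error")
      }
      out <- rep(NA_real_, length(y))
      out[ok] <- (res - mean(res)) / s
      metric_table[[col]][idx] <- out
    }
  }
  metric_table
}

#' Cohort-and-time model of staircase feedback rates
#'
#' For each adaptive-window task, fits OLS of the per-student feedback
#' percentage on cohort (two dummies) and linear time (numerator df 3) and
#' reports R-squared with a percentile-bootstrap confidence interval —
#' the descriptive check that the staircase, not age, sets challenge level.
#' Small R-squared values mean the adaptive window equated challenge across
#' cohorts and waves.
#'
#' @param feedback_table Long tibble with columns `task`, `feedback_pct`,
#'   `cohort`, `timepoint` (one row per student x timepoint x task). See
#'   [feedback_long()] for building it from a metric table.
#' @param n_boot Bootstrap replicates for the R-squared CI (default 999).
#' @param conf_level CI coverage (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @return A tibble with one row per task: `r_squared`, `f_statistic`,
#'   `df1`, `df2`, `p_value`, `ci_low`, `ci_high`, `n`.
#' @export
feedback_rate_model <- function(feedback_table, n_boot = 999,
                                conf_level = 0.95, seed = 1L) {
  stopifnot(all(c("task", "feedback_pct", "cohort", "timepoint") %in%
                  names(feedback_table)))
  one_task <- function(d) {
    d <- d[!is.na(d$feedback_pct), , drop = FALSE]
    d$cohort <- factor(d$cohort)
    fit <- lm(feedback_pct ~ cohort + timepoint, data = d)
    sm <- summary(fit)
    fstat <- sm$fstatistic
    boots <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(nrow(d), replace = TRUE)
        db <- d[i, ]
        if (length(unique(db$cohort)) < 2L || var(db$timepoint) == 0) {
          return(NA_real_)
        }
        summary(lm(feedback_pct ~ cohort + timepoint, data = db))$r.squared
      }, numeric(1))
    })
    alpha <- (1 - conf_level) / 2
    ci <- quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE)
    tibble::tibble(
      r_squared = sm$r.squared,
      f_statistic = unname(fstat["value"]),
      df1 = unname(fstat["numdf"]),
      df2 = unname(fstat["dendf"]),
      p_value = pf(fstat["value"], fstat["numdf"], fstat["dendf"],
                   lower.tail = FALSE),
      ci_low = unname(ci[1]),
      ci_high = unname(ci[2]),
      n = nrow(d)
    )
  }
  feedback_table |>
    dplyr::group_by(.data$task) |>
    dplyr::group_modify(~ one_task(.x)) |>
    dplyr::ungroup()
}

#' Reshape per-task feedback-rate columns to long format
#'
#' @param metric_table Metric tibble with `feedback_rate_*` columns from
#'   [build_metric_table()].
#' @return Long tibble with `task`, `feedback_pct` and the session keys,
#'   ready for [feedback_rate_model()].
#' @export
feedback_long <- function(metric_table) {
  fb_cols <- grep("^feedback_rate_", names(metric_table), value = TRUE)
  if (!length(fb_cols)) {
    abort("no feedback_rate_* columns found", class = "efnet_adjust_error")
  }
  col_of <- task_metric_column()
  task_of <- setNames(names(col_of), paste0("feedback_rate_", unname(col_of)))
  metric_table |>
    dplyr::select(dplyr::any_of(c("student_id", "cohort", "timepoint")),
                  dplyr::all_of(fb_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(fb_cols), names_to = "fb_col",
                        values_to = "feedback_pct") |>
    dplyr::mutate(task = unname(task_of[.data$fb_col])) |>
    dplyr::select(-"fb_col")
}
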