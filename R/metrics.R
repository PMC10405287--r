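# Task metrics of interest: one scalar per (student, timepoint, task).

#' Signal-detection sensitivity with log-linear correction
#'
#' `d' = z(H) - z(F)` where hit and false-alarm rates are corrected by the
#' log-linear rule (0.5 added to every cell) so extreme counts never produce
#' infinite quantiles.
#'
#' @param hits,misses,false_alarms,correct_rejections Non-negative counts.
#' @return A finite numeric scalar, increasing in the hit rate and
#'   decreasing in the false-alarm rate.
#' @export
#' @examples
#' dprime(80, 20, 20, 80) # about 1.66
#' dprime(10, 0, 0, 10)   # extreme rates stay finite
dprime <- function(hits, misses, false_alarms, correct_rejections) {
  stopifnot(hits >= 0, misses >= 0, false_alarms >= 0,
            correct_rejections >= 0)
  if ((hits + misses) == 0 || (false_alarms + correct_rejections) == 0) {
    abort("d-prime needs at least one signal and one noise trial",
          class = "efnet_metric_error")
  }
  h <- (hits + 0.5) / (hits + misses + 1)
  f <- (false_alarms + 0.5) / (false_alarms + correct_rejections + 1)
  qnorm(h) - qnorm(f)
}

#' Rate Correct Score
#'
#' Correct responses per second of average responding: the number of correct
#' responses divided by the product of mean RT (seconds, over all responded
#' trials) and the number of responded trials. Integrates speed and accuracy
#' without difference scores.
#'
#' @param trials Trial tibble with `rt_ms` and `correct`.
#' @return Numeric scalar (responses per second), `>= 0`.
#' @export
#' @examples
#' t <- tibble::tibble(rt_ms = rep(500, 25), correct = rep(c(TRUE, FALSE), c(20, 5)))
#' rate_correct_score(t) # 1.6
rate_correct_score <- function(trials) {
  responded <- trials[!is.na(trials$rt_ms), ]
  n_resp <- nrow(responded)
  if (n_resp == 0L) {
    abort("rate-correct score undefined with zero responded trials",
          class = "efnet_metric_error")
  }
  n_correct <- sum(responded$correct)
  if (n_correct == 0L) {
    return(0)
  }
  mean_rt_s <- mean(responded$rt_ms) / 1000
  n_correct / (mean_rt_s * n_resp)
}

#' RT variability to infrequent targets
#'
#' Sample standard deviation (n - 1 denominator) of response times on
#' correct target responses — the sustained-attention metric, sensitive to
#' attentional lapses.
#'
#' @param trials Trial tibble with `rt_ms`, `correct`, `is_target`.
#' @param target_condition Optional condition filter.
#' @return Numeric scalar in ms.
#' @export
rt_variability <- function(trials, target_condition = NULL) {
  if (!is.null(target_condition)) {
    trials <- trials[trials$condition %in% target_condition, ]
  }
  use <- trials$correct & !is.na(trials$rt_ms)
  if (!is.null(trials$is_target)) {
    use <- use & !is.na(trials$is_target) & trials$is_target
  }
  rts <- trials$rt_ms[use]
  if (length(rts) < 2L) {
    abort("RT variability needs at least two correct target responses",
          class = "efnet_metric_error")
  }
  sd(rts)
}

#' Span length
#'
#' Maximum sequence length attempted across a span task's trials.
#'
#' @param trials Trial tibble with `span_length_attempted`.
#' @return Integer scalar.
#' @export
span_length <- function(trials) {
  lens <- trials$span_length_attempted
  lens <- lens[!is.na(lens)]
  if (length(lens) == 0L) {
    abort("no span attempts in trials", class = "efnet_metric_error")
  }
  as.integer(max(lens))
}

#' Mean response time
#'
#' @param trials Trial tibble with `rt_ms` and `correct`.
#' @param filter `"all_responses"` (default) or `"correct_only"`.
#' @return Mean RT in ms over the filtered responded trials.
#' @export
mean_rt <- function(trials, filter = c("all_responses", "correct_only")) {
  filter <- match.arg(filter)
  use <- !is.na(trials$rt_ms)
  if (filter == "correct_only") {
    use <- use & trials$correct
  }
  if (!any(use)) {
    abort("no responded trials after filtering", class = "efnet_metric_error")
  }
  mean(trials$rt_ms[use])
}

#' Percentage of responses with "correct" feedback
#'
#' The challenge-level readout of the adaptive response window: 100 times
#' the share of responded trials whose feedback was `"correct"` (correct and
#' inside the deadline). The staircase is designed to hold this near
#' `100 * step_up / (step_up + step_down)` for every student.
#'
#' @param trials Trial tibble with `rt_ms` and `feedback`.
#' @return Numeric percentage in `[0, 100]`.
#' @export
feedback_rate <- function(trials) {
  responded <- !is.na(trials$rt_ms)
  if (!any(responded)) {
    abort("feedback rate undefined with zero responded trials",
          class = "efnet_metric_error")
  }
  100 * sum(trials$feedback[responded] == "correct") / sum(responded)
}

# metric for one task block; NA when the block cannot support its metric
task_metric <- function(task, trials) {
  tryCatch(
    switch(task,
      BRT = mean_rt(trials, "all_responses"),
      ForwardSpan = as.numeric(span_length(trials)),
      BackwardSpan = as.numeric(span_length(trials)),
      SustainedAttention = rt_variability(trials),
      ImpulsiveAttention = dprime(
        sum(trials$is_target & !is.na(trials$rt_ms), na.rm = TRUE),
        sum(trials$is_target & is.na(trials$rt_ms), na.rm = TRUE),
        sum(!trials$is_target & !is.na(trials$rt_ms), na.rm = TRUE),
        sum(!trials$is_target & is.na(trials$rt_ms), na.rm = TRUE)),
      TapAndTrace = {
        dual <- trials[trials$condition == "dual", ]
        if (nrow(dual) == 0L) {
          abort("no dual-task block", class = "efnet_metric_error")
        }
        dprime(sum(dual$is_target & !is.na(dual$rt_ms), na.rm = TRUE),
               sum(dual$is_target & is.na(dual$rt_ms), na.rm = TRUE),
               sum(!dual$is_target & !is.na(dual$rt_ms), na.rm = TRUE),
               sum(!dual$is_target & is.na(dual$rt_ms), na.rm = TRUE))
      },
      Stroop = rate_correct_score(trials),
      Flanker = rate_correct_score(trials),
      Boxed = mean_rt(trials, "correct_only")
    ),
    efnet_metric_error = function(e) NA_real_
  )
}

task_metric_column <- function() {
  c(BRT = "brt_mean_rt",
    ForwardSpan = "forward_span", BackwardSpan = "backward_span",
    SustainedAttention = "sustained_rt_sd",
    ImpulsiveAttention = "impulsive_dprime", TapAndTrace = "tap_trace_dprime",
    Stroop = "stroop_rcs", Flanker = "flanker_rcs", Boxed = "boxed_mean_rt")
}

#' Build the metric table from trial-level data
#'
#' Reduces a long trial table to one row per (student, timepoint) with one
#' column per task metric of interest, per-task feedback rates for the
#' adaptive-window tasks, and session covariates. Tap-and-trace d' uses the
#' dual-task block only; metrics whose task block is missing (or cannot
#' support the metric) are `NA`. The reduction is a pure function of its
#' input.
#'
#' @param trials Long trial tibble from [simulate_trials()] (or the same
#'   schema read from CSV).
#' @return A metric tibble keyed by `student_id`, `cohort`, `timepoint`.
#' @export
build_metric_table <- function(trials) {
  key_cols <- intersect(
    c("student_id", "cohort", "gender", "school_id", "timepoint",
      "months_since_first", "age_months"), names(trials))
  col_of <- task_metric_column()
  window_tasks <- c("SustainedAttention", "ImpulsiveAttention", "TapAndTrace",
                    "Stroop", "Flanker", "Boxed")
  nested <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(key_cols[key_cols != "task"], "task")))) |>
    tidyr::nest() |>
    dplyr::ungroup()
  nested$metric <- purrr::map2_dbl(nested$task, nested$data, task_metric)
  nested$fb <- purrr::map2_dbl(nested$task, nested$data, function(tk, d) {
    if (!tk %in% window_tasks) {
      return(NA_real_)
    }
    tryCatch(feedback_rate(d), efnet_metric_error = function(e) NA_real_)
  })
  metrics <- nested |>
    dplyr::mutate(column = unname(col_of[.data$task])) |>
    dplyr::select(dplyr::all_of(key_cols), "column", "metric") |>
    tidyr::pivot_wider(names_from = "column", values_from = "metric")
  fb <- nested |>
    dplyr::filter(.data$task %in% window_tasks) |>
    dplyr::mutate(column = paste0("feedback_rate_", unname(col_of[.data$task]))) |>
    dplyr::select(dplyr::all_of(key_cols), "column", "fb") |>
    tidyr::pivot_wider(names_from = "column", values_from = "fb")
  out <- dplyr::left_join(metrics, fb, by = key_cols)
  for (col in c(unname(col_of), paste0("feedback_rate_", unname(col_of[window_tasks])))) {
    if (!col %in% names(out)) {
      out[[col]] <- NA_real_
    }
  }
  dplyr::arrange(out, .data$cohort, .data$timepoint, .data$student_id)
}
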