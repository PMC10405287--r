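#' The default adaptive EF task battery
#'
#' One row per task: the basic response-time task (`BRT`, the
#' processing-speed covariate) plus eight EF tasks spanning working memory
#' (forward/backward spatial span), context monitoring (sustained and
#' impulsive attention from a continuous-performance test, and the dual-task
#' tap-and-trace) and interference resolution (Stroop, flanker, and the boxed
#' visual-search task). `adaptive` says which staircase governs the task:
#' `response_window` (a per-trial RT deadline that shrinks on correct
#' in-window responses), `span` (sequence length grows with performance) or
#' `none`.
#'
#' @param config An [ef_config()]; `config$trials` entries named after a task
#'   override its per-condition trial counts (recycled across conditions).
#' @return A tibble with columns `task`, `component` (`WM`/`CM`/`IR` or `NA`
#'   for BRT), `adaptive`, `response_type` (`gonogo`, `choice`, `simple`),
#'   `chance` (accuracy of guessing on the easiest condition; `NA` where an
#'   accuracy criterion does not apply) and a `conditions` list-column of
#'   tibbles (`condition`, `n_trials`, `p_target`, `easiest`, `acc_shift`,
#'   `rt_shift`).
#' @export
task_battery <- function(config = ef_config()) {
  cond <- function(condition, n_trials, p_target = NA_real_, easiest = FALSE,
                   acc_shift = 0, rt_shift = 0) {
    tibble::tibble(condition = condition, n_trials = as.integer(n_trials),
                   p_target = p_target, easiest = easiest,
                   acc_shift = acc_shift, rt_shift = rt_shift)
  }
  battery <- tibble::tribble(
    ~task, ~component, ~adaptive, ~response_type, ~chance, ~conditions,
    "BRT", NA_character_, "none", "simple", NA_real_,
    dplyr::bind_rows(cond("dominant", 20, easiest = TRUE),
                     cond("nondominant", 20, rt_shift = 0.05)),
    "ForwardSpan", "WM", "span", "recall", NA_real_,
    cond("forward", NA),
    "BackwardSpan", "WM", "span", "recall", NA_real_,
    cond("backward", NA, acc_shift = -0.5),
    "SustainedAttention", "CM", "response_window", "gonogo", 0.5,
    cond("target_infrequent", 90, p_target = 0.2, easiest = TRUE),
    "ImpulsiveAttention", "CM", "response_window", "gonogo", 0.5,
    cond("target_frequent", 90, p_target = 0.8, easiest = TRUE),
    "TapAndTrace", "CM", "response_window", "gonogo", 0.5,
    dplyr::bind_rows(
      cond("tap_single", 24, p_target = 0.5, easiest = TRUE),
      cond("dual", 36, p_target = 0.5, acc_shift = -0.4, rt_shift = 0.06)),
    "Stroop", "IR", "response_window", "choice", 0.25,
    dplyr::bind_rows(
      cond("congruent", 28, p_target = 0.7, easiest = TRUE),
      cond("incongruent", 12, p_target = 0.3, acc_shift = -0.5, rt_shift = 0.08)),
    "Flanker", "IR", "response_window", "choice", 0.5,
    dplyr::bind_rows(
      cond("congruent", 20, p_target = 0.5, easiest = TRUE),
      cond("incongruent", 20, p_target = 0.5, acc_shift = -0.5, rt_shift = 0.08)),
    "Boxed", "IR", "response_window", "choice", 0.5,
    dplyr::bind_rows(
      cond("feature_low", 12, easiest = TRUE),
      cond("feature_high", 12, acc_shift = -0.2, rt_shift = 0.05),
      cond("conjunction_low", 12, acc_shift = -0.3, rt_shift = 0.10),
      cond("conjunction_high", 12, acc_shift = -0.5, rt_shift = 0.18))
  )
  if (length(config$trials)) {
    battery$conditions <- purrr::map2(battery$task, battery$conditions,
      function(tk, cd) {
        if (!is.null(config$trials[[tk]])) {
          cd$n_trials <- as.integer(rep(config$trials[[tk]],
                                        length.out = nrow(cd)))
        }
        cd
      })
  }
  battery
}

# effective task ability: Common EF plus the task's specific component,
# weighted so the composite stays near unit variance
effective_ability <- function(profile_row, component, months = 0) {
  gr <- profile_row$growth * months
  g <- profile_row$g + gr
  spec <- switch(component,
                 WM = profile_row$wm, CM = profile_row$cm,
                 IR = profile_row$ir, 0) + gr
  0.5 * g + 0.85 * spec
}

#' Simulate one adaptive response-window task
#'
#' Runs the 1-up/1-down weighted staircase: the response deadline shrinks by
#' `step_down_ms` after every response that is correct and inside the window
#' ("correct" feedback) and grows by `step_up_ms` after any other response
#' ("late" or "incorrect" feedback), floored at a positive minimum.
#' No-response trials (withholds and misses in go/no-go tasks, lapses in
#' choice tasks) leave the window unchanged, so the long-run fraction of
#' responses earning "correct" feedback converges to
#' `step_up / (step_up + step_down)` — 75% with the default 30/10 ms steps —
#' at any ability level. Response times follow a shifted lognormal whose
#' location scales with the student's latent speed and decreases with the
#' task-relevant ability; accuracy follows a Gaussian signal-detection model
#' (go/no-go) or a logistic model (choice).
#'
#' @param profile One row of [simulate_population()] output.
#' @param spec One row of [task_battery()] (must have
#'   `adaptive == "response_window"`).
#' @param config An [ef_config()] (staircase and speed settings).
#' @param seed Integer seed; output is deterministic given it.
#' @param months Months since the student's first session (advances
#'   abilities by `growth`).
#' @param n_trials Optional override of the total trial count (split across
#'   conditions proportionally).
#' @return A tibble of trial records: `task`, `condition`, `trial_index`,
#'   `is_target`, `response_expected`, `rt_ms` (`NA` when no response),
#'   `correct`, `feedback` (`correct`/`late`/`incorrect`/`none`),
#'   `window_ms` (deadline in force on that trial), `span_length_attempted`
#'   (`NA` here).
#' @export
#' @examples
#' cfg <- ef_config(n_per_cohort = c(G34 = 1, G56 = 0, G78 = 0))
#' pop <- simulate_population(cfg)
#' spec <- dplyr::filter(task_battery(cfg), task == "Stroop")
#' trials <- simulate_adaptive_window_task(pop[1, ], spec, cfg, seed = 1)
#' feedback_rate(trials)
simulate_adaptive_window_task <- function(profile, spec, config, seed,
                                          months = 0, n_trials = NULL) {
  stopifnot(nrow(spec) == 1L, spec$adaptive == "response_window")
  sc <- config$staircase
  if (sc$floor_ms <= 0) {
    abort("window floor must be positive", class = "efnet_config_error")
  }
  conds <- spec$conditions[[1]]
  if (!is.null(n_trials)) {
    conds$n_trials <- pmax(1L, as.integer(round(
      n_trials * conds$n_trials / sum(conds$n_trials))))
  }
  theta <- effective_ability(profile, spec$component, months)
  gonogo <- spec$response_type == "gonogo"
  withr::with_seed(as.integer(seed), {
    cond_idx <- sample(rep.int(seq_len(nrow(conds)), conds$n_trials))
    n <- length(cond_idx)
    acc_shift <- conds$acc_shift[cond_idx]
    rt_shift <- conds$rt_shift[cond_idx]
    p_target <- conds$p_target[cond_idx]
    # pre-draw all stochastic components; the loop only tracks the window
    rt_draw <- 180 + rlnorm(n, log(profile$speed) + rt_shift - 0.10 * theta, 0.30)
    if (gonogo) {
      is_target <- runif(n) < p_target
      d <- pmax(0.1, 2.5 + 0.5 * theta + acc_shift)
      # base-rate-aware criterion: observers respond more readily when
      # targets are frequent and hold back when they are rare
      crit <- d / 2 + log((1 - p_target) / p_target) / d
      ev <- rnorm(n, mean = ifelse(is_target, d, 0))
      responded <- ev > crit
      correct <- responded == is_target
      response_expected <- FALSE
    } else {
      is_target <- NA
      responded <- runif(n) > 0.02 # rare response lapses
      # accuracy stays high across the ability range: the deadline, not
      # error rate, is what the staircase uses to set challenge
      p_corr <- stats::plogis(stats::qlogis(0.95) + 0.3 * theta + acc_shift)
      correct <- responded & (runif(n) < p_corr)
      response_expected <- TRUE
    }
    window <- numeric(n)
    feedback <- character(n)
    w <- sc$window_init_ms
    for (t in seq_len(n)) {
      window[t] <- w
      if (!responded[t]) {
        feedback[t] <- "none"
      } else if (!correct[t]) {
        feedback[t] <- "incorrect"
        w <- w + sc$step_up_ms
      } else if (rt_draw[t] <= w) {
        feedback[t] <- "correct"
        w <- max(sc$floor_ms, w - sc$step_down_ms)
      } else {
        feedback[t] <- "late"
        w <- w + sc$step_up_ms
      }
    }
    tibble::tibble(
      task = spec$task,
      condition = conds$condition[cond_idx],
      trial_index = seq_len(n) - 1L,
      is_target = if (gonogo) is_target else rep(NA, n),
      response_expected = response_expected,
      rt_ms = ifelse(responded, rt_draw, NA_real_),
      correct = correct,
      feedback = feedback,
      window_ms = window,
      span_length_attempted = NA_integer_
    )
  })
}

#' Simulate one adaptive span task
#'
#' Sequence length starts at `config$span$start`, increases by one after each
#' correct reproduction, and the task ends once the student has failed
#' `config$span$fail_limit` times at the same length (or the cap is
#' reached). Per-attempt success probability is a logistic function of the
#' gap between the student's working-memory ability and the length demand.
#'
#' @inheritParams simulate_adaptive_window_task
#' @param spec One row of [task_battery()] with `adaptive == "span"`.
#' @param success_prob Optional `function(length)` returning the success
#'   probability, overriding the ability model (used for calibration
#'   checks).
#' @return A tibble of trial records as in
#'   [simulate_adaptive_window_task()], with `span_length_attempted` filled
#'   and `window_ms` `NA`.
#' @export
simulate_span_task <- function(profile, spec, config, seed, months = 0,
                               success_prob = NULL) {
  stopifnot(nrow(spec) == 1L, spec$adaptive == "span")
  sp <- config$span
  theta <- effective_ability(profile, spec$component, months)
  acc_shift <- spec$conditions[[1]]$acc_shift[1]
  p_success <- success_prob %||%
    function(len) stats::plogis(1.5 * (theta + acc_shift - (len - 4.5)))
  withr::with_seed(as.integer(seed), {
    rec <- list()
    # staircase blocks: +1 length per success, stop after `fail_limit`
    # failures at one length; a fresh block starts at the base length until
    # the minimum attempt count is met (multi-block administration)
    repeat {
      len <- sp$start
      fails_at <- 0L
      repeat {
        ok <- runif(1) < p_success(len)
        rt <- len * (250 + rlnorm(1, log(profile$speed) - 0.10 * theta, 0.30) / 2)
        rec[[length(rec) + 1L]] <- list(len = len, ok = ok, rt = rt)
        if (ok) {
          if (len >= sp$max) break
          len <- len + 1L
          fails_at <- 0L
        } else {
          fails_at <- fails_at + 1L
          if (fails_at >= sp$fail_limit) break
        }
      }
      if (length(rec) >= sp$min_trials) break
    }
    n <- length(rec)
    tibble::tibble(
      task = spec$task,
      condition = spec$conditions[[1]]$condition[1],
      trial_index = seq_len(n) - 1L,
      is_target = NA,
      response_expected = TRUE,
      rt_ms = vapply(rec, `[[`, numeric(1), "rt"),
      correct = vapply(rec, `[[`, logical(1), "ok"),
      feedback = ifelse(vapply(rec, `[[`, logical(1), "ok"),
                        "correct", "incorrect"),
      window_ms = NA_real_,
      span_length_attempted = vapply(rec, function(r) as.integer(r$len),
                                     integer(1))
    )
  })
}

# basic response-time task: no staircase, no ability effect beyond speed
simulate_brt_task <- function(profile, spec, config, seed, months = 0) {
  conds <- spec$conditions[[1]]
  withr::with_seed(as.integer(seed), {
    cond_idx <- rep.int(seq_len(nrow(conds)), conds$n_trials)
    n <- length(cond_idx)
    rt <- 180 + rlnorm(n, log(profile$speed) + conds$rt_shift[cond_idx], 0.25)
    tibble::tibble(
      task = spec$task,
      condition = conds$condition[cond_idx],
      trial_index = seq_len(n) - 1L,
      is_target = NA,
      response_expected = TRUE,
      rt_ms = rt,
      correct = TRUE,
      feedback = "correct",
      window_ms = NA_real_,
      span_length_attempted = NA_integer_
    )
  })
}

#' Simulate one assessment session
#'
#' Runs the full battery (BRT plus the eight EF tasks) for one student at one
#' timepoint. Latent abilities are advanced by `growth` times the elapsed
#' months, so younger cohorts — configured with larger growth — improve
#' faster (the age-by-time interaction). The first session is always indexed
#' at zero months.
#'
#' @param profile One row of [simulate_population()].
#' @param timepoint Integer in `1..config$n_timepoints`.
#' @param config An [ef_config()].
#' @param battery Optional precomputed [task_battery()].
#' @return A tibble of trial records for all tasks with session columns
#'   `student_id`, `cohort`, `gender`, `school_id`, `timepoint`,
#'   `months_since_first`, `age_months` prepended.
#' @export
simulate_session <- function(profile, timepoint, config,
                             battery = task_battery(config)) {
  stopifnot(nrow(profile) == 1L)
  timepoint <- as.integer(timepoint)
  if (is.na(timepoint) || timepoint < 1L || timepoint > config$n_timepoints) {
    abort(sprintf("timepoint must be in 1..%d", config$n_timepoints),
          class = "efnet_config_error")
  }
  months <- (timepoint - 1L) * config$session_gap_months
  blocks <- purrr::map(seq_len(nrow(battery)), function(i) {
    spec <- battery[i, ]
    seed_i <- fan_seed(config$seed,
                       paste("session", profile$student_id, timepoint, spec$task))
    switch(spec$adaptive,
           response_window = simulate_adaptive_window_task(
             profile, spec, config, seed_i, months = months),
           span = simulate_span_task(profile, spec, config, seed_i,
                                     months = months),
           none = simulate_brt_task(profile, spec, config, seed_i,
                                    months = months))
  })
  trials <- dplyr::bind_rows(blocks)
  dplyr::bind_cols(
    tibble::tibble(
      student_id = profile$student_id,
      cohort = profile$cohort,
      gender = profile$gender,
      school_id = profile$school_id,
      timepoint = timepoint,
      months_since_first = months,
      age_months = profile$age_months_at_entry + months
    )[rep(1L, nrow(trials)), ],
    trials
  )
}

#' Simulate the full accelerated longitudinal trial dataset
#'
#' All students, all timepoints, before missingness. For cohort-scale runs
#' prefer modest `n_per_cohort`; trial-level simulation is meant for
#' exercising the metric/QC stages, while [generate_metric_dataset()] serves
#' the network/CFA stages directly.
#'
#' @param config An [ef_config()].
#' @param population Optional precomputed [simulate_population()].
#' @return A long trial tibble (one row per trial).
#' @export
simulate_trials <- function(config, population = simulate_population(config)) {
  battery <- task_battery(config)
  sessions <- purrr::map(seq_len(nrow(population)), function(i) {
    purrr::map(seq_len(config$n_timepoints), function(tp) {
      simulate_session(population[i, ], tp, config, battery)
    })
  })
  dplyr::bind_rows(purrr::flatten(sessions))
}

#' Mask sessions and task blocks at random
#'
#' Applies missing-completely-at-random masking: whole sessions are dropped
#' with `missing_session_rate`, then remaining individual task blocks with
#' `missing_task_rate`. Works on long trial tables (rows removed) or on
#' metric tables (cells set to `NA`).
#'
#' @param x A trial tibble from [simulate_trials()] or a metric table from
#'   [build_metric_table()]/[generate_metric_dataset()].
#' @param config An [ef_config()].
#' @param seed Optional seed override (defaults to a fan-out of
#'   `config$seed`).
#' @return Same type as `x`.
#' @export
apply_missingness <- function(x, config, seed = NULL) {
  seed <- seed %||% fan_seed(config$seed, "missingness")
  rs <- config$missing_session_rate
  rt <- config$missing_task_rate
  if (rs == 0 && rt == 0) {
    return(x)
  }
  metric_cols <- intersect(ef_metric_columns(), names(x))
  is_metric_table <- length(metric_cols) > 0 && !"trial_index" %in% names(x)
  withr::with_seed(as.integer(seed), {
    if (is_metric_table) {
      keep_session <- runif(nrow(x)) >= rs
      x <- x[keep_session, , drop = FALSE]
      for (col in c("brt_mean_rt", metric_cols)) {
        if (col %in% names(x)) {
          x[[col]][runif(nrow(x)) < rt] <- NA_real_
        }
      }
      x
    } else {
      sessions <- dplyr::distinct(x, .data$student_id, .data$timepoint)
      sessions <- sessions[runif(nrow(sessions)) >= rs, ]
      x <- dplyr::semi_join(x, sessions, by = c("student_id", "timepoint"))
      blocks <- dplyr::distinct(x, .data$student_id, .data$timepoint, .data$task)
      blocks <- blocks[runif(nrow(blocks)) >= rt, ]
      dplyr::semi_join(x, blocks,
                       by = c("student_id", "timepoint", "task"))
    }
  })
}
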