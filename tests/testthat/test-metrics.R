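# Task metrics of interest.

test_that("d-prime applies the log-linear correction and its symmetries", {
  # 80/100 hits, 20/100 false alarms -> corrected 0.797 / 0.203
  expect_equal(dprime(80, 20, 20, 80),
               qnorm(80.5 / 101) - qnorm(20.5 / 101))
  expect_equal(dprime(80, 20, 20, 80), 1.662, tolerance = 1e-3)
  # equal corrected rates
  expect_equal(dprime(7, 3, 7, 3), 0)
  # perfect performance stays finite under the correction
  expect_equal(dprime(10, 0, 0, 10), qnorm(10.5 / 11) - qnorm(0.5 / 11))
  expect_equal(dprime(10, 0, 0, 10), 3.3812, tolerance = 1e-4)
  # antisymmetry: swapping signal and noise counts negates d'
  expect_equal(dprime(18, 2, 6, 14), -dprime(6, 14, 18, 2))
  # monotone in hits, antitone in false alarms
  expect_gt(dprime(19, 1, 6, 14), dprime(18, 2, 6, 14))
  expect_lt(dprime(18, 2, 7, 13), dprime(18, 2, 6, 14))
  expect_error(dprime(0, 0, 5, 5), class = "efnet_metric_error")
})

test_that("rate-correct score follows its defining arithmetic", {
  t1 <- tibble::tibble(rt_ms = rep(500, 25),
                       correct = rep(c(TRUE, FALSE), c(20, 5)))
  expect_equal(rate_correct_score(t1), 1.6)
  t2 <- tibble::tibble(rt_ms = rep(600, 40),
                       correct = rep(c(TRUE, FALSE), c(30, 10)))
  expect_equal(rate_correct_score(t2), 1.25)
  # zero correct
  t3 <- tibble::tibble(rt_ms = rep(400, 5), correct = rep(FALSE, 5))
  expect_equal(rate_correct_score(t3), 0)
  # order invariance
  set.seed(1)
  t4 <- tibble::tibble(rt_ms = runif(30, 300, 900),
                       correct = runif(30) < 0.8)
  expect_equal(rate_correct_score(t4), rate_correct_score(t4[sample(30), ]))
  # scales inversely with mean RT at fixed accuracy
  t5 <- dplyr::mutate(t4, rt_ms = rt_ms * 2)
  expect_equal(rate_correct_score(t5), rate_correct_score(t4) / 2)
  # undefined without responses
  t6 <- tibble::tibble(rt_ms = NA_real_, correct = FALSE)
  expect_error(rate_correct_score(t6), class = "efnet_metric_error")
})

test_that("RT variability is the n-1 standard deviation of correct target RTs", {
  tr <- tibble::tibble(rt_ms = c(500, 600, 700), correct = TRUE,
                       is_target = TRUE, condition = "c")
  expect_equal(rt_variability(tr), 100)
  tr2 <- tibble::tibble(rt_ms = c(400, 400, 700), correct = TRUE,
                        is_target = TRUE, condition = "c")
  expect_equal(rt_variability(tr2), sqrt(30000))
  expect_equal(rt_variability(tr2), 173.2, tolerance = 1e-3)
  # constant RTs
  tr3 <- tibble::tibble(rt_ms = rep(550, 4), correct = TRUE,
                        is_target = TRUE, condition = "c")
  expect_equal(rt_variability(tr3), 0)
  # non-target and incorrect trials are ignored
  tr4 <- dplyr::bind_rows(tr, tibble::tibble(rt_ms = 5000, correct = FALSE,
                                             is_target = TRUE,
                                             condition = "c"),
                          tibble::tibble(rt_ms = 5000, correct = TRUE,
                                         is_target = FALSE, condition = "c"))
  expect_equal(rt_variability(tr4), 100)
  expect_error(rt_variability(tr[1, ]), class = "efnet_metric_error")
})

test_that("span length is the maximum attempted length", {
  tr <- tibble::tibble(span_length_attempted = c(2L, 3L, 4L, 5L, 5L))
  expect_equal(span_length(tr), 5L)
  expect_equal(span_length(tibble::tibble(span_length_attempted = 2L)), 2L)
})

test_that("higher ability earns longer spans in expectation", {
  cfg <- ef_config(seed = 1)
  spec <- battery_spec("ForwardSpan", cfg)
  lo <- vapply(1:40, function(i) {
    span_length(simulate_span_task(profile_with(-1), spec, cfg, seed = i))
  }, integer(1))
  hi <- vapply(1:40, function(i) {
    span_length(simulate_span_task(profile_with(1), spec, cfg,
                                   seed = 500 + i))
  }, integer(1))
  expect_gt(mean(hi), mean(lo) + 0.5)
})

test_that("mean RT pools and filters as requested", {
  tr <- tibble::tibble(rt_ms = c(300, 500), correct = c(TRUE, TRUE))
  expect_equal(mean_rt(tr), 400)
  tr2 <- tibble::tibble(rt_ms = c(300, 900), correct = c(TRUE, FALSE))
  expect_equal(mean_rt(tr2, "correct_only"), 300)
  # both hands pooled
  brt <- tibble::tibble(rt_ms = c(400, 420, 480, 500), correct = TRUE,
                        condition = rep(c("dominant", "nondominant"), each = 2))
  expect_equal(mean_rt(brt), 450)
})

test_that("feedback rate is the percentage of responses with correct feedback", {
  tr <- tibble::tibble(rt_ms = c(rep(500, 100), NA),
                       feedback = c(rep("correct", 75), rep("late", 15),
                                    rep("incorrect", 10), "none"))
  expect_equal(feedback_rate(tr), 75)
  expect_error(feedback_rate(tibble::tibble(rt_ms = NA_real_,
                                            feedback = "none")),
               class = "efnet_metric_error")
})

test_that("the metric table has one row per session with the right gaps", {
  cfg <- small_config(n = 4, seed = 11, missing_session_rate = 0,
                      missing_task_rate = 0)
  trials <- simulate_trials(cfg)
  mt <- build_metric_table(trials)
  expect_tibble(mt)
  expect_equal(nrow(mt), 4 * 3 * cfg$n_timepoints)
  metric_cols <- c("brt_mean_rt", "forward_span", "backward_span",
                   "sustained_rt_sd", "impulsive_dprime", "tap_trace_dprime",
                   "stroop_rcs", "flanker_rcs", "boxed_mean_rt")
  expect_true(all(metric_cols %in% names(mt)))
  expect_true(all(!is.na(mt$brt_mean_rt)))
  expect_true(all(mt$forward_span >= 2, na.rm = TRUE))
  expect_true(all(mt$stroop_rcs >= 0, na.rm = TRUE))

  # purely functional: same input, same table
  expect_identical(mt, build_metric_table(trials))

  # tap-and-trace without a dual block yields an absent cell
  single_only <- dplyr::filter(trials,
                               !(task == "TapAndTrace" & condition == "dual"))
  mt2 <- build_metric_table(single_only)
  expect_true(all(is.na(mt2$tap_trace_dprime)))
  expect_false(all(is.na(mt2$impulsive_dprime)))
})
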