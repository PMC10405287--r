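# Synthetic cohort generators: population, staircases, sessions, metric
# datasets, missingness.

test_that("population draws match the configured design", {
  cfg <- ef_config(n_per_cohort = c(G34 = 300, G56 = 150, G78 = 0),
                   seed = 42)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop), 450L)
  expect_false(any(pop$cohort == "G78"))

  g34 <- pop[pop$cohort == "G34", ]
  se <- 4.2 / sqrt(300)
  expect_lt(abs(mean(g34$age_months_at_entry) - 96.8), 3 * se)

  # determinism: same seed, identical roster
  expect_identical(pop, simulate_population(cfg))
  # different seed, different draws
  pop2 <- simulate_population(ef_config(n_per_cohort = c(G34 = 300, G56 = 150,
                                                         G78 = 0), seed = 43))
  expect_false(identical(pop$age_months_at_entry, pop2$age_months_at_entry))
})

test_that("latent abilities carry the configured correlation structure", {
  cfg <- ef_config(n_per_cohort = c(G34 = 0, G56 = 0, G78 = 5000),
                   seed = 7, gender_effect = 0)
  pop <- simulate_population(cfg)
  ab <- as.matrix(pop[, c("g", "wm", "cm", "ir")])
  expect_lt(max(abs(cor(ab) - default_ability_corr())), 0.05)
})

test_that("invalid configurations are rejected", {
  bad_corr <- matrix(1, 4, 4) # singular
  expect_error(ef_config(ability_corr = bad_corr), class = "efnet_config_error")
  expect_error(ef_config(missing_task_rate = 1.5), class = "efnet_config_error")
  expect_error(ef_config(window_floor_ms = 0), class = "efnet_config_error")
  expect_error(ef_config(loading_general = 0.9, loading_specific = 0.9),
               class = "efnet_config_error")
})

test_that("response-window staircase settles at the step-ratio target", {
  cfg <- ef_config(seed = 1)
  spec <- battery_spec("Stroop", cfg)
  pr <- profile_with(ability = 0)
  tr <- simulate_adaptive_window_task(pr, spec, cfg, seed = 21,
                                      n_trials = 5000)
  expect_equal(feedback_rate(tr), 75, tolerance = 2 / 75)

  # symmetric steps halve the target
  cfg_sym <- ef_config(seed = 1, step_up_ms = 10, step_down_ms = 10)
  tr_sym <- simulate_adaptive_window_task(pr, spec, cfg_sym, seed = 21,
                                          n_trials = 5000)
  expect_equal(feedback_rate(tr_sym), 50, tolerance = 2 / 50)
})

test_that("ability moves the equilibrium window, not the feedback rate", {
  cfg <- ef_config(seed = 1)
  spec <- battery_spec("Flanker", cfg)
  lo <- profile_with(ability = -1.5)
  hi <- profile_with(ability = 1.5)
  tr_lo <- simulate_adaptive_window_task(lo, spec, cfg, seed = 8,
                                         n_trials = 4000)
  tr_hi <- simulate_adaptive_window_task(hi, spec, cfg, seed = 8,
                                         n_trials = 4000)
  # equilibrium window (after burn-in) shrinks with ability
  expect_lt(mean(tail(tr_hi$window_ms, 1000)),
            mean(tail(tr_lo$window_ms, 1000)) - 50)
  # challenge level is equated
  expect_equal(feedback_rate(tr_lo), 75, tolerance = 2 / 75)
  expect_equal(feedback_rate(tr_hi), 75, tolerance = 2 / 75)
})

test_that("window-task records respect the feedback contract", {
  cfg <- ef_config(seed = 1)
  tr <- simulate_adaptive_window_task(profile_with(0),
                                      battery_spec("ImpulsiveAttention", cfg),
                                      cfg, seed = 3, n_trials = 800)
  ok <- tr$feedback == "correct"
  expect_true(all(tr$correct[ok] & tr$rt_ms[ok] <= tr$window_ms[ok]))
  late <- tr$feedback == "late"
  expect_true(all(tr$correct[late] & tr$rt_ms[late] > tr$window_ms[late]))
  expect_true(all(is.na(tr$rt_ms[tr$feedback == "none"])))
  expect_true(all(tr$window_ms >= cfg$staircase$floor_ms))
  # determinism
  tr2 <- simulate_adaptive_window_task(profile_with(0),
                                       battery_spec("ImpulsiveAttention", cfg),
                                       cfg, seed = 3, n_trials = 800)
  expect_identical(tr, tr2)
})

test_that("span staircase follows the up-one / stop-on-two-failures rule", {
  cfg <- ef_config(seed = 1)
  spec <- battery_spec("ForwardSpan", cfg)
  pr <- profile_with(0)
  # succeeds up to length 6, then always fails: attempts 2..7, 7 again
  tr <- simulate_span_task(pr, spec, cfg, seed = 5,
                           success_prob = function(len) as.numeric(len <= 6))
  expect_equal(span_length(tr), 7L)
  expect_equal(sum(!tr$correct), 2L)
  expect_equal(tr$span_length_attempted[!tr$correct], c(7L, 7L))

  # never succeeds: max attempted stays at the starting length
  tr0 <- simulate_span_task(pr, spec, cfg, seed = 5,
                            success_prob = function(len) 0)
  expect_equal(span_length(tr0), cfg$span$start)
  # minimum administration is honored
  expect_gte(nrow(tr0), cfg$span$min_trials)
  # determinism
  expect_identical(tr, simulate_span_task(pr, spec, cfg, seed = 5,
                                          success_prob = function(len)
                                            as.numeric(len <= 6)))
})

test_that("sessions assemble the battery and index time from first assessment", {
  cfg <- small_config(n = 2, missing_session_rate = 0, missing_task_rate = 0)
  pop <- simulate_population(cfg)
  s1 <- simulate_session(pop[1, ], 1, cfg)
  expect_setequal(unique(s1$task),
                  c("BRT", "ForwardSpan", "BackwardSpan", "SustainedAttention",
                    "ImpulsiveAttention", "TapAndTrace", "Stroop", "Flanker",
                    "Boxed"))
  expect_equal(unique(s1$months_since_first), 0)
  s3 <- simulate_session(pop[1, ], 3, cfg)
  expect_equal(unique(s3$months_since_first), 2 * cfg$session_gap_months)
  expect_error(simulate_session(pop[1, ], 9, cfg),
               class = "efnet_config_error")
})

test_that("positive growth improves expected performance across timepoints", {
  cfg <- small_config(n = 30, seed = 404,
                      growth_per_month = c(G34 = 0.05, G56 = 0.05, G78 = 0.05),
                      missing_session_rate = 0, missing_task_rate = 0)
  pop <- simulate_population(cfg)
  pop <- pop[pop$cohort == "G34", ]
  spec <- battery_spec("ImpulsiveAttention", cfg)
  d1 <- vapply(seq_len(nrow(pop)), function(i) {
    tr <- simulate_adaptive_window_task(pop[i, ], spec, cfg,
                                        seed = 1000 + i, months = 0)
    dprime(sum(tr$is_target & !is.na(tr$rt_ms)),
           sum(tr$is_target & is.na(tr$rt_ms)),
           sum(!tr$is_target & !is.na(tr$rt_ms)),
           sum(!tr$is_target & is.na(tr$rt_ms)))
  }, numeric(1))
  d4 <- vapply(seq_len(nrow(pop)), function(i) {
    tr <- simulate_adaptive_window_task(pop[i, ], spec, cfg,
                                        seed = 2000 + i, months = 18)
    dprime(sum(tr$is_target & !is.na(tr$rt_ms)),
           sum(tr$is_target & is.na(tr$rt_ms)),
           sum(!tr$is_target & !is.na(tr$rt_ms)),
           sum(!tr$is_target & is.na(tr$rt_ms)))
  }, numeric(1))
  expect_gt(mean(d4 - d1), 0)
})

test_that("metric datasets converge to the implied covariance", {
  cfg <- ef_config(seed = 9, structural_drift = c(G34 = 0, G56 = 0, G78 = 0))
  d <- generate_metric_dataset(cfg, "G78", 1, n = 10000)
  truth <- attr(d, "structure")
  x <- as.matrix(d[, names(truth$communities)])
  expect_lt(max(abs(cor(x) - truth$sigma)), 0.03)
  # k = 1: a single planted community
  cfg1 <- ef_config(seed = 9, structure = list(
    G34 = list(k = 1L), G56 = list(k = 3L), G78 = list(k = 3L)))
  d1 <- generate_metric_dataset(cfg1, "G34", 1, n = 50)
  expect_equal(unname(attr(d1, "structure")$communities), rep(0L, 8))
  # zero loadings: metrics mutually independent
  cfg0 <- ef_config(seed = 9, loading_general = 1e-6,
                    loading_specific = 1e-6,
                    structural_drift = c(G34 = 0, G56 = 0, G78 = 0))
  d0 <- generate_metric_dataset(cfg0, "G78", 1, n = 4000)
  c0 <- cor(as.matrix(d0[, ef_metric_columns()]))
  expect_lt(max(abs(c0[upper.tri(c0)])), 0.06)
})

test_that("missingness masks at the configured rates", {
  cfg <- ef_config(seed = 2, missing_session_rate = 0,
                   missing_task_rate = 0.2)
  d <- generate_metric_dataset(cfg, "G56", 1, n = 5000)
  masked <- apply_missingness(d, cfg)
  frac <- mean(is.na(masked$stroop_rcs))
  expect_equal(frac, 0.2, tolerance = 3 * sqrt(0.2 * 0.8 / 5000) / 0.2)

  # zero rates: identity
  cfg0 <- ef_config(seed = 2, missing_session_rate = 0, missing_task_rate = 0)
  expect_identical(apply_missingness(d, cfg0), d)

  # rate 1 for tasks: every metric cell absent
  cfg1 <- ef_config(seed = 2, missing_session_rate = 0, missing_task_rate = 1)
  gone <- apply_missingness(d, cfg1)
  expect_true(all(is.na(gone$flanker_rcs)))
})

test_that("config YAML round-trips", {
  cfg <- ef_config(n_per_cohort = c(G34 = 10, G56 = 20, G78 = 30), seed = 77,
                   step_up_ms = 24, missing_task_rate = 0.03)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ef_config(cfg, path)
  cfg2 <- read_ef_config(path)
  expect_equal(cfg2$cohorts, cfg$cohorts)
  expect_equal(cfg2$staircase, cfg$staircase)
  expect_equal(cfg2$structure, cfg$structure)
  expect_equal(cfg2$seed, cfg$seed)
})
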