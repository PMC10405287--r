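# Exclusion cascade: trial filter, inclusion rule, MAD and Cook's flags.

test_that("trial filter drops anticipations and expected-but-absent responses", {
  tr <- tibble::tibble(
    rt_ms = c(150, 200, 500, NA, NA),
    response_expected = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    feedback = "none"
  )
  out <- filter_trials(tr)
  # 150 ms anticipatory dropped; 200 ms boundary kept; expected no-response
  # dropped; go/no-go withhold kept
  expect_equal(out$rt_ms, c(200, 500, NA))
  expect_equal(attr(out, "dropped"),
               c(no_response = 1L, anticipatory = 1L))
})

test_that("inclusion requires five responded trials per condition", {
  cfg <- ef_config()
  spec <- battery_spec("Flanker", cfg)
  mk <- function(n_cong, n_incong, acc = 1) {
    tibble::tibble(
      condition = rep(c("congruent", "incongruent"), c(n_cong, n_incong)),
      rt_ms = 500,
      correct = runif(n_cong + n_incong) < acc
    )
  }
  set.seed(4)
  expect_true(task_inclusion(mk(20, 20), spec))
  expect_false(task_inclusion(mk(20, 4), spec))
})

test_that("inclusion applies the exact binomial above-chance rule", {
  cfg <- ef_config()
  spec <- battery_spec("Flanker", cfg) # chance 0.5, easiest congruent
  mk <- function(x, n) {
    tibble::tibble(
      condition = c(rep("congruent", n), rep("incongruent", n)),
      rt_ms = 500,
      correct = c(rep(c(TRUE, FALSE), c(x, n - x)), rep(TRUE, n))
    )
  }
  # 20/20 correct at chance 0.5: clearly above chance
  expect_true(task_inclusion(mk(20, 20), spec))
  # 13/20: exact binomial tail P(X >= 13) = 0.132 > 0.05 -> excluded
  expect_equal(binom.test(13, 20, 0.5, "greater")$p.value, 0.1316, tolerance = 1e-3)
  expect_false(task_inclusion(mk(13, 20), spec))
  # 15/20: P = 0.021 < 0.05 -> included
  expect_true(task_inclusion(mk(15, 20), spec))
})

test_that("MAD flags follow the 3-MAD rule with the 1.4826 constant", {
  x <- c(1:9, 100)
  # median 5.5, scaled MAD 1.4826 * 2.5 = 3.7065, bound 5.5 +/- 11.12
  expect_equal(mad(x), 3.7065, tolerance = 1e-4)
  expect_equal(which(mad_outliers(x)), 10L)
  # all equal: nothing flagged
  expect_false(any(mad_outliers(rep(5, 8))))
  # degenerate MAD: any value off the median is flagged
  expect_equal(mad_outliers(c(5, 5, 5, 5, 6)), c(F, F, F, F, T))
  # well-behaved data: nothing flagged
  expect_false(any(mad_outliers(c(-2, -1, 0, 1, 2))))
  # NA values are never flagged
  expect_false(mad_outliers(c(x, NA))[11])
})

test_that("MAD flagging is invariant under affine transforms", {
  set.seed(13)
  for (rep in 1:20) {
    x <- rnorm(40) + c(rep(0, 38), 5, -6)
    a <- runif(1, 0.1, 10)
    b <- runif(1, -100, 100)
    expect_identical(mad_outliers(x), mad_outliers(a * x + b))
    expect_identical(mad_outliers(x), mad_outliers(-a * x + b))
  }
})

test_that("Cook's distance flags gross-leverage points and only those", {
  set.seed(2)
  x <- 1:10
  y <- 2 * x + rnorm(10, 0, 0.3)
  y[10] <- 2 * x[10] + 40 # gross outlier at high leverage
  flags <- cooks_outliers(y, data.frame(x = x))
  expect_true(flags[10])
  expect_false(any(flags[1:9]))
  # a point exactly on the line has zero influence
  y2 <- 2 * x
  y2[5] <- 2 * x[5]
  expect_false(any(cooks_outliers(y2 + rnorm(10, 0, 0.2), data.frame(x = x))[5]))
  # oracle: flags agree with stats::cooks.distance on the same fit
  d <- data.frame(y = y, x = x)
  cd <- cooks.distance(lm(y ~ x, data = d))
  expect_identical(unname(cd > 1), cooks_outliers(y, data.frame(x = x)))
  # duplicating an inlier leaves flag status unchanged
  y3 <- c(y, y[3])
  x3 <- c(x, x[3])
  expect_true(cooks_outliers(y3, data.frame(x = x3))[10])
  expect_false(any(cooks_outliers(y3, data.frame(x = x3))[c(1:9, 11)]))
})

test_that("the QC cascade removes colorblind students wholly, others cell-wise", {
  cfg <- small_config(n = 25, seed = 5, colorblind_rate = 0.15,
                      missing_session_rate = 0, missing_task_rate = 0)
  pop <- simulate_population(cfg)
  trials <- simulate_trials(cfg, pop)
  mt <- build_metric_table(trials)
  res <- apply_qc(mt, trials, battery = task_battery(cfg), population = pop)
  cb <- pop$student_id[pop$colorblind]
  expect_gt(length(cb), 0)
  expect_false(any(res$table$student_id %in% cb))
  # non-colorblind flags blank only the offending cell
  flags <- res$report$flags
  cell_flags <- flags[flags$flag == "mad_outlier", ]
  if (nrow(cell_flags)) {
    i <- 1L
    row <- res$table[res$table$student_id == cell_flags$student_id[i] &
                       res$table$timepoint == cell_flags$timepoint[i], ]
    expect_true(is.na(row[[cell_flags$column[i]]]))
    expect_true(nrow(row) == 1L)
  }
  expect_true(res$report$excluded_fraction >= 0 &&
                res$report$excluded_fraction <= 1)
})

test_that("clean synthetic data loses under 5% of task cells", {
  cfg <- small_config(n = 40, seed = 6, colorblind_rate = 0,
                      missing_session_rate = 0, missing_task_rate = 0)
  trials <- simulate_trials(cfg)
  mt <- build_metric_table(trials)
  res <- apply_qc(mt, trials, battery = task_battery(cfg))
  expect_lt(res$report$excluded_fraction, 0.05)
})

test_that("QC is idempotent on an already-cleaned table", {
  cfg <- small_config(n = 40, seed = 8, colorblind_rate = 0,
                      missing_session_rate = 0, missing_task_rate = 0)
  trials <- simulate_trials(cfg)
  mt <- build_metric_table(trials)
  once <- apply_qc(mt, trials, battery = task_battery(cfg))
  twice <- apply_qc(once$table, trials, battery = task_battery(cfg))
  expect_equal(twice$table, once$table)
})
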