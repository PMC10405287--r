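# ML confirmatory factor analysis: fitting, fit indices, nested tests,
# redundancy, and the conservative selection rule.

implied_sigma <- function(lambda, phi, psi) {
  lambda %*% phi %*% t(lambda) + diag(psi)
}

three_factor_truth <- function(load = 0.7, phi_vals = c(0.4, 0.5, 0.3)) {
  pat <- cfa_structures()$F3
  lambda <- pat * load
  phi <- diag(3)
  phi[1, 2] <- phi[2, 1] <- phi_vals[1]
  phi[1, 3] <- phi[3, 1] <- phi_vals[2]
  phi[2, 3] <- phi[3, 2] <- phi_vals[3]
  psi <- rep(1 - load^2, 8)
  list(lambda = lambda, phi = phi, psi = psi,
       sigma = implied_sigma(lambda, phi, psi))
}

test_that("the five structures cover the theorized collapses", {
  st <- cfa_structures()
  expect_named(st, c("F1", "F2_IR_CM", "F2_WM_CM", "F2_WM_IR", "F3"))
  expect_true(all(vapply(st, function(p) all(rowSums(p) == 1), logical(1))))
  expect_equal(ncol(st$F1), 1L)
  expect_equal(ncol(st$F3), 3L)
  # in the IR-with-CM collapse, working memory stands alone
  expect_equal(sum(st$F2_IR_CM[, "WM"]), 2)
  expect_equal(sum(st$F2_IR_CM[, "CM_IR"]), 6)
})

test_that("a covariance equal to an implied structure fits perfectly", {
  truth <- three_factor_truth()
  fit <- fit_cfa(truth$sigma, n = 300, spec = "F3")
  expect_lt(fit$chisq, 1e-6)
  expect_equal(fit$cfi, 1)
  expect_equal(fit$rmsea, 0)
  expect_equal(fit$df, 17)
  expect_true(fit$converged)
  # parameters are recovered at the optimum
  expect_equal(unname(fit$loadings[fit$pattern == 1]), rep(0.7, 8),
               tolerance = 1e-4)
  expect_equal(unname(fit$factor_corr[1, 2]), 0.4, tolerance = 1e-4)
  expect_equal(unname(fit$uniqueness), rep(0.51, 8), tolerance = 1e-4)
})

test_that("RMSEA and the information criteria follow their formulas", {
  truth <- three_factor_truth()
  fit <- fit_cfa(truth$sigma, n = 201, spec = "F1")
  expect_equal(fit$rmsea,
               sqrt(max(fit$chisq - fit$df, 0) / (fit$df * 200)))
  expect_equal(fit$aic, fit$chisq + 2 * fit$n_free)
  expect_equal(fit$bicc, fit$chisq + log((201 + 2) / 24) * fit$n_free)
  # worked check of the RMSEA arithmetic: chisq 30, df 20, n 201 -> 0.05
  expect_equal(sqrt(max(30 - 20, 0) / (20 * 200)), 0.05)
})

test_that("analytic gradients match finite differences", {
  set.seed(81)
  truth <- three_factor_truth()
  s <- cov(MASS::mvrnorm(150, rep(0, 8), truth$sigma))
  dimnames(s) <- dimnames(truth$sigma)
  obj <- efnet:::cfa_objective(s, cfa_structures()$F3)
  theta <- c(rep(0.6, 8), rep(atanh(0.35), 3), rep(log(0.5), 8))
  g_analytic <- obj$gr(theta)
  h <- 1e-6
  g_numeric <- vapply(seq_along(theta), function(i) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h
    tm[i] <- tm[i] - h
    (obj$fn(tp) - obj$fn(tm)) / (2 * h)
  }, numeric(1))
  expect_equal(g_analytic, g_numeric, tolerance = 1e-5)
})

test_that("parameters are recovered from large simulated samples", {
  set.seed(82)
  truth <- three_factor_truth()
  x <- MASS::mvrnorm(10000, rep(0, 8), truth$sigma)
  s <- cov(x)
  dimnames(s) <- dimnames(truth$sigma)
  fit <- fit_cfa(s, n = 10000, spec = "F3")
  expect_true(fit$converged)
  expect_lt(max(abs(fit$loadings[fit$pattern == 1] - 0.7)), 0.05)
  expect_lt(max(abs(fit$factor_corr - truth$phi)), 0.05)
})

test_that("the fit is invariant to task column order", {
  set.seed(83)
  truth <- three_factor_truth()
  s <- cov(MASS::mvrnorm(400, rep(0, 8), truth$sigma))
  dimnames(s) <- dimnames(truth$sigma)
  fit <- fit_cfa(s, n = 400, spec = "F3")
  perm <- c(5, 1, 8, 2, 6, 3, 7, 4)
  fit_perm <- fit_cfa(s[perm, perm], n = 400, spec = "F3")
  expect_equal(fit_perm$chisq, fit$chisq, tolerance = 1e-6)
  expect_equal(fit_perm$loadings, fit$loadings, tolerance = 1e-4)
})

test_that("chi-square differences map to the tail function and check nesting", {
  # worked examples of the difference-distribution mapping
  expect_equal(round(lrt_pvalue(10.602, 1), 3), 0.001)
  expect_equal(round(lrt_pvalue(0.157, 1), 3), 0.692)
  set.seed(84)
  truth <- three_factor_truth()
  s <- cov(MASS::mvrnorm(300, rep(0, 8), truth$sigma))
  dimnames(s) <- dimnames(truth$sigma)
  fits <- fit_cfa_battery(s, 300)
  cmp <- chisq_difference(fits$F1, fits$F2_IR_CM)
  expect_equal(cmp$delta_df, 1L)
  expect_gte(cmp$delta_chisq, 0)
  cmp2 <- chisq_difference(fits$F2_WM_CM, fits$F3)
  expect_equal(cmp2$delta_df, 2L)
  expect_gte(cmp2$delta_chisq, 0)
  # a nested pair whose extra parameter buys nothing: delta 0, p = 1
  f1_same <- fits$F1
  f2_same <- fits$F2_IR_CM
  f2_same$chisq <- f1_same$chisq
  same <- chisq_difference(f1_same, f2_same)
  expect_equal(same$delta_chisq, 0)
  expect_equal(same$p_value, 1)
  # two-factor permutations are not nested in each other
  expect_error(chisq_difference(fits$F2_IR_CM, fits$F2_WM_CM),
               class = "efnet_cfa_error")
  expect_error(chisq_difference(fits$F3, fits$F1),
               class = "efnet_cfa_error")
})

test_that("factor redundancy uses a strict 0.70 threshold", {
  truth <- three_factor_truth(phi_vals = c(0.70, 0.9, 0.1))
  # exercise the rule on exact correlations, free of optimizer noise
  fit <- structure(list(
    factor_corr = `dimnames<-`(truth$phi, list(c("WM", "CM", "IR"),
                                               c("WM", "CM", "IR")))),
    class = "ef_cfa")
  red <- factor_redundancy(fit)
  expect_equal(nrow(red), 3L)
  at_threshold <- red[red$factor_a == "WM" & red$factor_b == "CM", ]
  expect_equal(at_threshold$correlation, 0.70, tolerance = 1e-3)
  expect_equal(at_threshold$shared_variance, 0.49, tolerance = 1e-3)
  expect_false(at_threshold$redundant)
  over <- red[red$factor_a == "WM" & red$factor_b == "IR", ]
  expect_true(over$redundant)
  expect_equal(over$shared_variance, 0.81, tolerance = 1e-3)
  under <- red[red$factor_a == "CM" & red$factor_b == "IR", ]
  expect_false(under$redundant)
  # a single-factor fit has no pairs
  f1 <- fit_cfa(truth$sigma, 500, "F1")
  expect_equal(nrow(factor_redundancy(f1)), 0L)
})

test_that("the conservative selection rule picks the right complexity", {
  fake_fit <- function(name, chisq, q) {
    pat <- cfa_structures()[[name]]
    structure(list(structure = name, pattern = pat, chisq = chisq,
                   n_free = q, aic = chisq + 2 * q),
              class = "ef_cfa")
  }
  q <- c(F1 = 16, F2_IR_CM = 17, F2_WM_CM = 17, F2_WM_IR = 17, F3 = 19)
  # every comparison wildly significant -> F3
  fits_all <- purrr::imap(c(F1 = 200, F2_IR_CM = 100, F2_WM_CM = 100,
                            F2_WM_IR = 100, F3 = 20),
                          function(x, nm) fake_fit(nm, x, q[[nm]]))
  expect_equal(model_selection_report(fits_all)$selected, "F3")
  # no comparison significant -> F1
  fits_none <- purrr::imap(c(F1 = 20, F2_IR_CM = 19.8, F2_WM_CM = 19.9,
                             F2_WM_IR = 19.7, F3 = 19.5),
                           function(x, nm) fake_fit(nm, x, q[[nm]]))
  expect_equal(model_selection_report(fits_none)$selected, "F1")
  # all two-factor models beat F1, F3 never preferred -> best 2-factor by AIC
  fits_two <- purrr::imap(c(F1 = 120, F2_IR_CM = 60, F2_WM_CM = 50,
                            F2_WM_IR = 70, F3 = 49),
                          function(x, nm) fake_fit(nm, x, q[[nm]]))
  sel <- model_selection_report(fits_two)
  expect_equal(sel$selected, "F2_WM_CM")
  expect_equal(nrow(sel$comparisons), 6L)
})

test_that("simulated three-factor strata select the three-factor model", {
  set.seed(85)
  truth <- three_factor_truth(load = 0.7, phi_vals = c(0.45, 0.5, 0.35))
  picks <- vapply(1:10, function(i) {
    s <- rWishart(1, 449, truth$sigma)[, , 1] / 449
    dimnames(s) <- dimnames(truth$sigma)
    model_selection_report(fit_cfa_battery(s, 450))$selected
  }, character(1))
  expect_gte(mean(picks == "F3"), 0.9)
})
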