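# Confirmatory factor analysis of the competing EF structures: one
# undifferentiated factor, the three two-factor collapses, and the full
# three-factor model, fit by normal-theory ML on the covariance matrix.

#' The five competing EF factor structures
#'
#' Simple-structure patterns over the 8 task metrics: `F1` (a single
#' undifferentiated EF factor), the three two-factor models in which one
#' theorized pair of components is collapsed (`F2_IR_CM` collapses
#' interference resolution with context monitoring, leaving working memory
#' distinct, and so on), and `F3` (working memory, context monitoring and
#' interference resolution fully differentiated). Every task loads on
#' exactly one factor.
#'
#' @return Named list of binary loading-pattern matrices (8 rows, K
#'   columns).
#' @export
cfa_structures <- function() {
  comp <- ef_component_map()
  tasks <- ef_metric_columns()
  groups_of <- function(groups) {
    k <- length(groups)
    pat <- matrix(0, length(tasks), k, dimnames = list(tasks, names(groups)))
    for (j in seq_len(k)) {
      pat[tasks[comp[tasks] %in% groups[[j]]], j] <- 1
    }
    pat
  }
  list(
    F1 = groups_of(list(EF = c("WM", "CM", "IR"))),
    F2_IR_CM = groups_of(list(WM = "WM", CM_IR = c("CM", "IR"))),
    F2_WM_CM = groups_of(list(WM_CM = c("WM", "CM"), IR = "IR")),
    F2_WM_IR = groups_of(list(WM_IR = c("WM", "IR"), CM = "CM")),
    F3 = groups_of(list(WM = "WM", CM = "CM", IR = "IR"))
  )
}

# the component partition a pattern encodes, used for nesting checks
pattern_partition <- function(pattern) {
  lapply(seq_len(ncol(pattern)), function(j) rownames(pattern)[pattern[, j] == 1])
}

# ML discrepancy and analytic gradient for a simple-structure CFA with unit
# factor variances. theta = c(lambda[8], phi[K(K-1)/2], log(psi)[8]); factor
# correlations are unconstrained (the implied covariance must stay positive
# definite, which the objective enforces), so likelihood-ratio tests against
# collapsed-factor models are not boundary-limited.
cfa_objective <- function(s, pattern) {
  p <- nrow(pattern)
  k <- ncol(pattern)
  factor_of <- apply(pattern, 1L, which.max)
  n_phi <- k * (k - 1L) / 2L
  phi_idx <- which(upper.tri(diag(k)), arr.ind = TRUE)
  logdet_s <- determinant(s, logarithm = TRUE)$modulus

  unpack <- function(theta) {
    lambda_v <- theta[seq_len(p)]
    phi <- diag(k)
    if (n_phi > 0) {
      u <- theta[p + seq_len(n_phi)]
      phi[phi_idx] <- u
      phi[phi_idx[, c(2L, 1L), drop = FALSE]] <- u
    }
    psi <- exp(theta[p + n_phi + seq_len(p)])
    lambda <- matrix(0, p, k)
    lambda[cbind(seq_len(p), factor_of)] <- lambda_v
    list(lambda = lambda, phi = phi, psi = psi)
  }

  implied <- function(par) {
    par$lambda %*% par$phi %*% t(par$lambda) + diag(par$psi)
  }

  fn <- function(theta) {
    par <- unpack(theta)
    sigma <- implied(par)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) {
      return(1e10)
    }
    inv <- chol2inv(ch)
    val <- 2 * sum(log(diag(ch))) + sum(inv * s) - logdet_s - p
    as.numeric(val)
  }

  gr <- function(theta) {
    par <- unpack(theta)
    sigma <- implied(par)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) {
      return(rep(0, length(theta)))
    }
    inv <- chol2inv(ch)
    g <- inv - inv %*% s %*% inv # dF = tr(g dSigma)
    glp <- g %*% par$lambda %*% par$phi
    grad_lambda <- 2 * glp[cbind(seq_len(p), factor_of)]
    grad_phi <- numeric(n_phi)
    if (n_phi > 0) {
      for (m in seq_len(n_phi)) {
        j <- phi_idx[m, 1L]
        l <- phi_idx[m, 2L]
        grad_phi[m] <- 2 * as.numeric(
          t(par$lambda[, j]) %*% g %*% par$lambda[, l])
      }
    }
    grad_psi <- diag(g) * par$psi
    c(grad_lambda, grad_phi, grad_psi)
  }

  list(fn = fn, gr = gr, unpack = unpack, implied = implied,
       p = p, k = k, n_phi = n_phi, factor_of = factor_of)
}

#' Fit one CFA structure by normal-theory maximum likelihood
#'
#' Minimizes the ML discrepancy
#' `F = log|Sigma(theta)| + tr(S Sigma^-1) - log|S| - p` over loadings,
#' factor correlations and uniquenesses, with factor variances fixed at 1
#' (so factor correlations are free and reportable). Optimization uses
#' analytic gradients with up to `restarts` jittered restarts. Reports
#' `chisq = (n - 1) * F` and the usual fit indices: CFI against the
#' independence baseline, RMSEA, AIC (`chisq + 2q`) and the sample-size
#' adjusted BIC (`chisq + log((n + 2) / 24) * q`).
#'
#' @param s 8 x 8 sample covariance matrix (positive definite).
#' @param n Sample size behind `s` (must exceed the number of variables).
#' @param spec A pattern matrix from [cfa_structures()] or one of its names.
#' @param restarts Additional jittered starts if the first fit fails or to
#'   guard against local minima (default 3).
#' @return An `ef_cfa`: `loadings`, `factor_corr`, `uniqueness`, `fml`,
#'   `chisq`, `df`, `p_value`, `cfi`, `rmsea`, `aic`, `bicc`, `n`,
#'   `n_free`, `converged`, `heywood`, `structure`.
#' @export
fit_cfa <- function(s, n, spec, restarts = 3L) {
  if (is.character(spec)) {
    spec_name <- spec
    spec <- cfa_structures()[[spec]]
    if (is.null(spec)) {
      abort(sprintf("unknown structure '%s'", spec_name),
            class = "efnet_cfa_error")
    }
  } else {
    spec_name <- attr(spec, "name") %||% NA_character_
  }
  s <- as.matrix(s)
  p <- nrow(spec)
  stopifnot(nrow(s) == p, ncol(s) == p, n > p)
  if (!is.null(rownames(s))) {
    # fit is invariant to input column order; align to the pattern's order
    if (!setequal(rownames(s), rownames(spec))) {
      abort("covariance row names do not match the structure's variables",
            class = "efnet_cfa_error")
    }
    s <- s[rownames(spec), rownames(spec)]
  }
  chol_pd(s, "sample covariance")
  obj <- cfa_objective(s, spec)
  k <- obj$k
  start <- c(0.7 * sqrt(diag(s)), rep(0.3, obj$n_phi),
             log(0.5 * diag(s)))
  best <- NULL
  seeds_jitter <- seq_len(restarts)
  for (attempt in c(0L, seeds_jitter)) {
    th0 <- if (attempt == 0L) start else {
      withr::with_seed(attempt, start + rnorm(length(start), 0, 0.2))
    }
    fit <- tryCatch(
      nlminb(th0, obj$fn, gradient = obj$gr,
             control = list(iter.max = 500L, eval.max = 1000L)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    if (is.null(best) || fit$objective < best$objective - 1e-10) {
      best <- fit
    }
    if (attempt == 0L && fit$convergence == 0L) break
  }
  if (is.null(best)) {
    abort("CFA optimization failed from all starts", class = "efnet_cfa_error")
  }
  par <- obj$unpack(best$par)
  # factor sign indeterminacy: orient each factor's loadings positive
  for (j in seq_len(k)) {
    if (sum(par$lambda[, j]) < 0) {
      par$lambda[, j] <- -par$lambda[, j]
      par$phi[j, -j] <- -par$phi[j, -j]
      par$phi[-j, j] <- -par$phi[-j, j]
    }
  }
  dimnames(par$lambda) <- dimnames(spec)
  dimnames(par$phi) <- list(colnames(spec), colnames(spec))
  names(par$psi) <- rownames(spec)
  fml <- best$objective
  q <- p + obj$n_phi + p
  df <- p * (p + 1L) / 2L - q
  chisq <- (n - 1) * fml
  # independence baseline: diagonal implied covariance
  f_base <- as.numeric(sum(log(diag(s))) -
                         determinant(s, logarithm = TRUE)$modulus)
  chisq_base <- (n - 1) * f_base
  df_base <- p * (p - 1L) / 2L
  cfi_den <- max(chisq_base - df_base, chisq - df, 0)
  cfi <- if (cfi_den == 0) 1 else 1 - max(chisq - df, 0) / cfi_den
  rmsea <- sqrt(max(chisq - df, 0) / (df * (n - 1)))
  heywood <- any(par$psi < 1e-3 * diag(s))
  structure(list(
    structure = spec_name,
    pattern = spec,
    loadings = par$lambda,
    factor_corr = par$phi,
    uniqueness = par$psi,
    fml = fml,
    chisq = chisq,
    df = df,
    p_value = pchisq(chisq, df, lower.tail = FALSE),
    cfi = cfi,
    rmsea = rmsea,
    aic = chisq + 2 * q,
    bicc = chisq + log((n + 2) / 24) * q,
    n = n,
    n_free = q,
    converged = best$convergence == 0L && !heywood,
    heywood = heywood
  ), class = "ef_cfa")
}

#' @export
print.ef_cfa <- function(x, ...) {
  cat(sprintf("<ef_cfa> %s: chisq(%d) = %.3f, p = %.3g\n",
              x$structure %||% "custom", x$df, x$chisq, x$p_value))
  cat(sprintf("  CFI %.3f | RMSEA %.3f | AIC %.1f | BICc %.1f | n = %d%s\n",
              x$cfi, x$rmsea, x$aic, x$bicc, x$n,
              if (x$heywood) " [Heywood]" else ""))
  invisible(x)
}

#' Upper-tail p-value of a chi-square difference
#'
#' The mapping from a likelihood-ratio difference statistic and its df
#' difference to a p-value.
#'
#' @param delta_chisq Non-negative difference statistic.
#' @param delta_df Positive integer df difference.
#' @return Upper-tail probability.
#' @export
#' @examples
#' lrt_pvalue(10.602, 1) # 0.001 at 3 d.p.
lrt_pvalue <- function(delta_chisq, delta_df) {
  stopifnot(delta_df >= 1)
  pchisq(delta_chisq, delta_df, lower.tail = FALSE)
}

#' Likelihood-ratio test between nested CFA fits
#'
#' The nested (more constrained, fewer factors) model's factor partition
#' must be a coarsening of the comparison model's. Under plain ML the
#' difference statistic is never negative for truly nested fits at their
#' optima.
#'
#' @param nested,comparison `ef_cfa` fits on the same data.
#' @return A tibble row: `delta_chisq`, `delta_df`, `p_value`.
#' @export
chisq_difference <- function(nested, comparison) {
  stopifnot(inherits(nested, "ef_cfa"), inherits(comparison, "ef_cfa"))
  part_n <- pattern_partition(nested$pattern)
  part_c <- pattern_partition(comparison$pattern)
  coarser <- all(vapply(part_c, function(grp) {
    any(vapply(part_n, function(sup) all(grp %in% sup), logical(1)))
  }, logical(1)))
  if (!coarser || nested$n_free >= comparison$n_free) {
    abort("models are not nested (nested must coarsen comparison's factors)",
          class = "efnet_cfa_error")
  }
  delta <- nested$chisq - comparison$chisq
  ddf <- comparison$n_free - nested$n_free
  tibble::tibble(delta_chisq = delta, delta_df = ddf,
                 p_value = lrt_pvalue(max(delta, 0), ddf))
}

#' Flag redundant factor pairs
#'
#' Factor correlations strictly above the threshold (0.70 by default, i.e.
#' more than 49% shared variance) indicate components that are not really
#' differentiated.
#'
#' @param fit An `ef_cfa`.
#' @param threshold Redundancy cutoff on `|phi|` (default 0.70).
#' @return A tibble: `factor_a`, `factor_b`, `correlation`,
#'   `shared_variance`, `redundant`.
#' @export
factor_redundancy <- function(fit, threshold = 0.70) {
  phi <- fit$factor_corr
  k <- ncol(phi)
  if (k < 2L) {
    return(tibble::tibble(factor_a = character(), factor_b = character(),
                          correlation = numeric(),
                          shared_variance = numeric(), redundant = logical()))
  }
  idx <- which(upper.tri(phi), arr.ind = TRUE)
  tibble::tibble(
    factor_a = colnames(phi)[idx[, 1L]],
    factor_b = colnames(phi)[idx[, 2L]],
    correlation = phi[idx],
    shared_variance = phi[idx]^2,
    redundant = abs(phi[idx]) > threshold
  )
}

#' Fit all five structures to one stratum
#'
#' @param s 8 x 8 sample covariance; or pass `adjusted_table` with
#'   `cohort`/`timepoint` to compute FIML moments first.
#' @param n Sample size.
#' @return Named list of five `ef_cfa` fits.
#' @export
fit_cfa_battery <- function(s, n) {
  structures <- cfa_structures()
  purrr::imap(structures, function(pat, nm) {
    attr(pat, "name") <- nm
    fit_cfa(s, n, pat)
  })
}

#' Model-comparison grid and conservative selection
#'
#' Runs the six nested comparisons (1-factor against each 2-factor model,
#' each 2-factor model against the 3-factor model) and applies the
#' conservative rule: the 3-factor model is selected only if it beats every
#' 2-factor permutation; a 2-factor model only if every permutation beats
#' the 1-factor model (the best 2-factor permutation by AIC is then
#' reported); otherwise the single-factor model is retained.
#'
#' @param fits Named list of five `ef_cfa` fits from [fit_cfa_battery()].
#' @param alpha Significance level for the difference tests (default 0.05).
#' @return A list: `comparisons` (tibble of the six tests) and `selected`
#'   (structure name).
#' @export
model_selection_report <- function(fits, alpha = 0.05) {
  two_factor <- c("F2_IR_CM", "F2_WM_CM", "F2_WM_IR")
  stopifnot(all(c("F1", two_factor, "F3") %in% names(fits)))
  rows <- list()
  for (f2 in two_factor) {
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(nested = "F1", comparison = f2),
      chisq_difference(fits$F1, fits[[f2]]))
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(nested = f2, comparison = "F3"),
      chisq_difference(fits[[f2]], fits$F3))
  }
  grid <- dplyr::bind_rows(rows)
  grid$significant <- grid$p_value < alpha
  f3_beats_all <- all(grid$significant[grid$comparison == "F3"])
  f2_beats_f1 <- all(grid$significant[grid$nested == "F1"])
  selected <- if (f3_beats_all) {
    "F3"
  } else if (f2_beats_f1) {
    aics <- vapply(fits[two_factor], function(f) f$aic, numeric(1))
    two_factor[which.min(aics)]
  } else {
    "F1"
  }
  list(comparisons = grid, selected = selected)
}

#' Reference chi-square difference table (published study)
#'
#' The printed model-comparison grid (difference statistics, df and
#' p-values for 12 cohort-by-timepoint strata and six nested comparisons)
#' from a published two-year accelerated longitudinal study of executive
#' functions in grades 3-8, bundled as a regression fixture for the
#' difference-distribution mapping.
#'
#' @return A tibble: `cohort`, `timepoint`, `n`, `comparison`,
#'   `delta_chisq`, `delta_df`, `p_printed` (string; `"<0.001"` where the
#'   table printed a bound).
#' @export
reference_chisq_comparisons <- function() {
  path <- system.file("extdata", "reference_chisq_comparisons.csv",
                      package = "efnet", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    colClasses = c(p_printed = "character")))
}
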