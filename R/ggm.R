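# Saturated Gaussian graphical model per cohort x timepoint: FIML moments
# under missing data, then partial correlations from the inverse covariance.

#' Full-information maximum-likelihood moments under missing data
#'
#' EM for the multivariate normal: per missingness pattern, the E-step fills
#' conditional means and covariances of the missing block given the observed
#' one; the M-step updates the mean vector and (denominator-n) covariance.
#' Iterates until the observed-data log-likelihood changes by less than
#' `tol`. With complete data this lands on the closed-form ML moments after
#' a single iteration, exactly.
#'
#' @param data Numeric matrix or data frame (rows = observations) with `NA`
#'   for missing cells; rows that are entirely missing are dropped.
#' @param tol Log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 5000).
#' @return A list: `mean`, `cov` (ML, denominator n), `loglik`
#'   (observed-data), `n`, `n_complete`, `iterations`, `converged`.
#' @export
#' @examples
#' x <- MASS::mvrnorm(50, c(0, 0), diag(2))
#' x[sample(100, 10)] <- NA
#' fiml_moments(x)$converged
fiml_moments <- function(data, tol = 1e-8, max_iter = 5000L) {
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  x <- x[rowSums(!is.na(x)) > 0L, , drop = FALSE]
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) {
    abort("need at least two rows with data", class = "efnet_ggm_error")
  }
  obs <- !is.na(x)
  if (any(colSums(obs) < 2L)) {
    abort("every variable must be observed in at least two rows",
          class = "efnet_ggm_error")
  }
  pair_cov <- crossprod(obs)
  if (any(pair_cov == 0L)) {
    bad <- which(pair_cov == 0L, arr.ind = TRUE)[1L, ]
    abort(sprintf("variables %d and %d are never jointly observed",
                  bad[1L], bad[2L]), class = "efnet_ggm_error")
  }
  pattern_id <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  patterns <- split(seq_len(n), pattern_id)
  complete_rows <- sum(pattern_id == paste(rep(1L, p), collapse = ""))

  # initial moments: observed-cell means, pairwise-complete covariance
  # (ridge-repaired if needed)
  mu <- colMeans(x, na.rm = TRUE)
  sigma <- cov(x, use = "pairwise.complete.obs")
  sigma[is.na(sigma)] <- 0
  d <- diag(sigma)
  d[d <= 0] <- 1
  diag(sigma) <- d
  while (inherits(tryCatch(chol(sigma), error = identity), "error")) {
    sigma <- 0.9 * sigma + 0.1 * diag(d)
  }

  loglik_obs <- function(mu, sigma) {
    ll <- 0
    for (rows in patterns) {
      o <- obs[rows[1L], ]
      ll <- ll + mvn_loglik(x[rows, o, drop = FALSE], mu[o],
                            sigma[o, o, drop = FALSE])
    }
    ll
  }

  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    t1 <- numeric(p)
    t2 <- matrix(0, p, p)
    for (rows in patterns) {
      o <- obs[rows[1L], ]
      m <- !o
      xo <- x[rows, o, drop = FALSE]
      if (!any(m)) {
        t1 <- t1 + colSums(xo)
        t2 <- t2 + crossprod(xo)
        next
      }
      soo_inv <- chol2inv(chol(sigma[o, o, drop = FALSE]))
      b <- sigma[m, o, drop = FALSE] %*% soo_inv
      xm_hat <- sweep(xo, 2L, mu[o]) %*% t(b)
      xm_hat <- sweep(xm_hat, 2L, mu[m], `+`)
      cond_cov <- sigma[m, m, drop = FALSE] - b %*% sigma[o, m, drop = FALSE]
      xfill <- matrix(0, length(rows), p)
      xfill[, o] <- xo
      xfill[, m] <- xm_hat
      t1 <- t1 + colSums(xfill)
      cp <- crossprod(xfill)
      cp[m, m] <- cp[m, m, drop = FALSE] + length(rows) * cond_cov
      t2 <- t2 + cp
    }
    mu <- t1 / n
    sigma <- t2 / n - tcrossprod(mu)
    sigma <- (sigma + t(sigma)) / 2
    ll <- loglik_obs(mu, sigma)
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
  }
  names(mu) <- colnames(x)
  dimnames(sigma) <- list(colnames(x), colnames(x))
  list(mean = mu, cov = sigma, loglik = ll, n = n,
       n_complete = complete_rows, iterations = iter, converged = converged)
}

#' Partial correlations from a covariance matrix
#'
#' Standardized negative inverse covariance:
#' `pcor_ij = -theta_ij / sqrt(theta_ii * theta_jj)` with unit diagonal —
#' the edge weights of the saturated Gaussian graphical model.
#'
#' @param covariance Symmetric positive-definite matrix.
#' @return Symmetric matrix with unit diagonal, off-diagonals in (-1, 1).
#' @export
#' @examples
#' partial_correlations(diag(3))
partial_correlations <- function(covariance) {
  covariance <- as.matrix(covariance)
  ch <- tryCatch(chol(covariance), error = function(e) {
    abort("covariance is singular; cannot condition on the remaining variables",
          class = "efnet_ggm_error")
  })
  theta <- chol2inv(ch)
  d <- sqrt(diag(theta))
  pcor <- -theta / tcrossprod(d)
  diag(pcor) <- 1
  dimnames(pcor) <- dimnames(covariance)
  pcor
}

#' Estimate the partial-correlation network of one stratum
#'
#' Runs [fiml_moments()] on the stratum's 8 adjusted metric columns and
#' converts the ML covariance to partial correlations. The model is
#' saturated (no regularization): every edge is estimated.
#'
#' @param adjusted_table Metric tibble (typically [residualize_on_brt()]
#'   output).
#' @param cohort,timepoint Stratum selector; omit both to use all rows.
#' @param columns Metric columns (default the 8 EF metrics).
#' @return An `ef_network`: `node_labels`, `mean`, `covariance`, `pcor`,
#'   `n_rows`, `n_complete`, `loglik`, `converged`, `cohort`, `timepoint`.
#' @export
estimate_network <- function(adjusted_table, cohort = NULL, timepoint = NULL,
                             columns = ef_metric_columns()) {
  d <- adjusted_table
  if (!is.null(cohort)) d <- d[d$cohort %in% cohort, , drop = FALSE]
  if (!is.null(timepoint)) d <- d[d$timepoint %in% timepoint, , drop = FALSE]
  missing_cols <- setdiff(columns, names(d))
  if (length(missing_cols)) {
    abort(paste("missing metric columns:", paste(missing_cols, collapse = ", ")),
          class = "efnet_ggm_error")
  }
  x <- as.matrix(d[, columns])
  fm <- fiml_moments(x)
  structure(list(
    node_labels = columns,
    mean = fm$mean,
    covariance = fm$cov,
    pcor = partial_correlations(fm$cov),
    n_rows = fm$n,
    n_complete = fm$n_complete,
    loglik = fm$loglik,
    converged = fm$converged,
    cohort = if (is.null(cohort)) NA_character_ else cohort[1L],
    timepoint = if (is.null(timepoint)) NA_integer_ else as.integer(timepoint[1L])
  ), class = "ef_network")
}

#' @export
print.ef_network <- function(x, ...) {
  cat(sprintf("<ef_network> %s t%s: %d nodes, n = %d (%d complete)%s\n",
              x$cohort, x$timepoint, length(x$node_labels), x$n_rows,
              x$n_complete,
              if (x$converged) "" else " [FIML did not converge]"))
  disp <- sum(abs(x$pcor[upper.tri(x$pcor)]) > 0.1)
  cat(sprintf("  |pcor| > 0.1 on %d of %d edges\n", disp,
              sum(upper.tri(x$pcor))))
  invisible(x)
}

#' All edges of a network, with display flags
#'
#' Every unordered node pair is returned; `displayed` marks edges whose
#' absolute weight exceeds the display threshold. The threshold is a
#' plotting convention only — every analysis uses the full matrix.
#'
#' @param network An `ef_network`.
#' @param display_threshold Absolute-weight display cutoff (default 0.1).
#' @return A tibble with `from`, `to`, `weight`, `displayed`.
#' @export
edge_list <- function(network, display_threshold = 0.1) {
  p <- network$pcor
  labels <- network$node_labels
  idx <- which(upper.tri(p), arr.ind = TRUE)
  tibble::tibble(
    from = labels[idx[, 1L]],
    to = labels[idx[, 2L]],
    weight = p[idx],
    displayed = abs(p[idx]) > display_threshold
  )
}

#' Serialize a network model as JSON
#'
#' @param network An `ef_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  jsonlite::write_json(list(
    node_labels = network$node_labels,
    cohort = network$cohort,
    timepoint = network$timepoint,
    mean = unname(network$mean),
    covariance = unname(as.data.frame(network$covariance)),
    pcor = unname(as.data.frame(network$pcor)),
    n_rows = network$n_rows,
    n_complete = network$n_complete,
    loglik = network$loglik,
    converged = network$converged
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
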