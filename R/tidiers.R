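# broom-style tidiers for the fitted objects.

#' Tidy a partial-correlation network
#'
#' @param x An `ef_network`.
#' @param display_threshold Threshold for the `displayed` flag.
#' @param ... Unused.
#' @return One row per edge: `from`, `to`, `weight`, `displayed`.
#' @method tidy ef_network
#' @export
tidy.ef_network <- function(x, display_threshold = 0.1, ...) {
  edge_list(x, display_threshold)
}

#' @rdname tidy.ef_network
#' @method glance ef_network
#' @export
glance.ef_network <- function(x, ...) {
  tibble::tibble(
    cohort = x$cohort, timepoint = x$timepoint,
    n_nodes = length(x$node_labels), n_rows = x$n_rows,
    n_complete = x$n_complete, loglik = x$loglik, converged = x$converged
  )
}

#' Tidy a community partition
#'
#' @param x An `ef_partition` or `ef_modal_partition`.
#' @param ... Unused.
#' @return One row per node: `node`, `community`.
#' @method tidy ef_partition
#' @export
tidy.ef_partition <- function(x, ...) {
  tibble::tibble(
    node = names(x$assignment) %||% as.character(seq_along(x$assignment)),
    community = unname(x$assignment)
  )
}

#' @rdname tidy.ef_partition
#' @method tidy ef_modal_partition
#' @export
tidy.ef_modal_partition <- function(x, ...) {
  tidy.ef_partition(x$modal)
}

#' @rdname tidy.ef_partition
#' @method glance ef_modal_partition
#' @export
glance.ef_modal_partition <- function(x, ...) {
  tibble::tibble(
    n_communities = x$modal$n_communities,
    frequency = x$frequency,
    n_runs = x$n_runs,
    n_distinct_partitions = nrow(x$distribution),
    hamiltonian = x$modal$hamiltonian
  )
}

#' Tidy a network-stability result
#'
#' @param x An `ef_stability`.
#' @param ... Unused.
#' @return One row per network pair: `network_a`, `network_b`, `r`,
#'   `ci_low`, `ci_high`.
#' @method tidy ef_stability
#' @export
tidy.ef_stability <- function(x, ...) {
  idx <- which(upper.tri(x$corr_matrix), arr.ind = TRUE)
  tibble::tibble(
    network_a = x$network_ids[idx[, 1L]],
    network_b = x$network_ids[idx[, 2L]],
    r = x$corr_matrix[idx],
    ci_low = x$ci_low[idx],
    ci_high = x$ci_high[idx]
  )
}

#' @rdname tidy.ef_stability
#' @method glance ef_stability
#' @export
glance.ef_stability <- function(x, ...) {
  x$anova
}

#' Tidy a CFA fit
#'
#' @param x An `ef_cfa`.
#' @param ... Unused.
#' @return One row per estimated parameter: `term`, `factor`, `estimate`,
#'   `type` (`loading`, `factor_correlation`, `uniqueness`).
#' @method tidy ef_cfa
#' @export
tidy.ef_cfa <- function(x, ...) {
  lam <- x$loadings
  factor_of <- colnames(lam)[apply(x$pattern, 1L, which.max)]
  loadings <- tibble::tibble(
    term = rownames(lam), factor = factor_of,
    estimate = lam[cbind(seq_len(nrow(lam)), apply(x$pattern, 1L, which.max))],
    type = "loading")
  phi <- x$factor_corr
  rows <- list(loadings)
  if (ncol(phi) > 1L) {
    idx <- which(upper.tri(phi), arr.ind = TRUE)
    rows[[2L]] <- tibble::tibble(
      term = paste(colnames(phi)[idx[, 1L]], colnames(phi)[idx[, 2L]],
                   sep = "~~"),
      factor = NA_character_, estimate = phi[idx],
      type = "factor_correlation")
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    term = names(x$uniqueness), factor = NA_character_,
    estimate = unname(x$uniqueness), type = "uniqueness")
  dplyr::bind_rows(rows)
}

#' @rdname tidy.ef_cfa
#' @method glance ef_cfa
#' @export
glance.ef_cfa <- function(x, ...) {
  tibble::tibble(
    structure = x$structure, chisq = x$chisq, df = x$df,
    p_value = x$p_value, cfi = x$cfi, rmsea = x$rmsea, aic = x$aic,
    bicc = x$bicc, n = x$n, n_free = x$n_free, converged = x$converged,
    heywood = x$heywood
  )
}
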