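# Community detection on signed partial-correlation networks.

# pull a weight matrix out of whatever the caller passed
as_weight_matrix <- function(network) {
  if (inherits(network, "ef_network")) {
    w <- network$pcor
    diag(w) <- 0
    return(w)
  }
  w <- as.matrix(network)
  stopifnot(nrow(w) == ncol(w))
  if (is.null(rownames(w))) {
    dimnames(w) <- list(paste0("V", seq_len(nrow(w))),
                        paste0("V", seq_len(nrow(w))))
  }
  diag(w) <- 0
  w
}

#' Signed Spinglass Hamiltonian of a partition
#'
#' The objective community detection minimizes:
#' `H = -sum_{i<j, same community} [(w+_ij - gamma_pos * p+_ij) -
#' (w-_ij - gamma_neg * p-_ij)]`, where `w+`/`w-` are the positive and
#' negative parts of the edge weights and `p+`/`p-` their
#' configuration-model null expectations. Negative edges inside a community
#' raise the energy, which is why this objective handles negative partial
#' correlations.
#'
#' @param network An `ef_network` or a symmetric weight matrix.
#' @param assignment Integer community labels (one per node).
#' @param gamma_pos,gamma_neg Resolution parameters for the positive and
#'   negative null terms (default 1).
#' @return Numeric scalar energy.
#' @export
signed_hamiltonian <- function(network, assignment, gamma_pos = 1,
                               gamma_neg = 1) {
  w <- as_weight_matrix(network)
  n <- nrow(w)
  stopifnot(length(assignment) == n)
  wp <- pmax(w, 0)
  wn <- pmax(-w, 0)
  sp <- rowSums(wp)
  sn <- rowSums(wn)
  mp <- sum(wp[upper.tri(wp)])
  mn <- sum(wn[upper.tri(wn)])
  pp <- if (mp > 0) tcrossprod(sp) / (2 * mp) else matrix(0, n, n)
  pn <- if (mn > 0) tcrossprod(sn) / (2 * mn) else matrix(0, n, n)
  a <- (wp - gamma_pos * pp) - (wn - gamma_neg * pn)
  same <- outer(assignment, assignment, `==`)
  -sum(a[upper.tri(a) & same])
}

#' Canonical relabeling of a community assignment
#'
#' Relabels communities by first appearance in node order, so label-switched
#' runs of a stochastic detector compare equal. Idempotent.
#'
#' @param assignment Integer (optionally named) community labels.
#' @return An `ef_partition`: `assignment` (canonical, 0-based),
#'   `n_communities`, `canonical = TRUE`.
#' @export
#' @examples
#' canonicalize(c(A = 2, B = 2, C = 7))$assignment
canonicalize <- function(assignment) {
  if (inherits(assignment, "ef_partition")) {
    assignment <- assignment$assignment
  }
  first <- unique(assignment)
  canon <- match(assignment, first) - 1L
  names(canon) <- names(assignment)
  structure(list(assignment = canon,
                 n_communities = length(first),
                 canonical = TRUE,
                 hamiltonian = NA_real_),
            class = "ef_partition")
}

#' @export
print.ef_partition <- function(x, ...) {
  cat(sprintf("<ef_partition> %d communities%s\n", x$n_communities,
              if (is.finite(x$hamiltonian))
                sprintf(" (H = %.4f)", x$hamiltonian) else ""))
  groups <- split(names(x$assignment) %||% seq_along(x$assignment),
                  x$assignment)
  for (g in names(groups)) {
    cat(sprintf("  [%s] %s\n", g, paste(groups[[g]], collapse = ", ")))
  }
  invisible(x)
}

#' Spinglass community detection on a signed network
#'
#' Minimizes the signed Potts Hamiltonian (see [signed_hamiltonian()]) by
#' simulated annealing: heat-bath single-spin updates with geometric cooling
#' followed by a zero-temperature descent. Deterministic given `seed`. The
#' full partial-correlation matrix is the input; no display threshold is
#' applied.
#'
#' @param network An `ef_network` or symmetric weight matrix.
#' @param gamma_pos,gamma_neg Resolution parameters (default 1).
#' @param n_spins Maximum number of communities (default: number of nodes).
#' @param seed Integer seed.
#' @param t_start,t_end,cooling Annealing schedule: initial and final
#'   temperature and geometric cooling factor.
#' @param sweeps_per_temp Heat-bath sweeps per temperature step.
#' @param restarts Independent annealing runs per call; the lowest-energy
#'   solution is returned (all driven by the one seed, so the call stays
#'   deterministic).
#' @return An `ef_partition` with the canonical assignment and its energy.
#' @export
spinglass_partition <- function(network, gamma_pos = 1, gamma_neg = 1,
                                n_spins = NULL, seed = 1L,
                                t_start = 1, t_end = 0.01, cooling = 0.99,
                                sweeps_per_temp = 1L, restarts = 12L) {
  w <- as_weight_matrix(network)
  n <- nrow(w)
  if (n < 2L) {
    abort("network needs at least two nodes", class = "efnet_community_error")
  }
  if (!all(is.finite(w))) {
    abort("edge weights must be finite", class = "efnet_community_error")
  }
  n_spins <- n_spins %||% n
  if (all(w == 0)) {
    warn("all edge weights are zero; returning a single community")
    part <- canonicalize(setNames(rep(0L, n), rownames(w)))
    part$hamiltonian <- 0
    return(part)
  }
  res <- spinglass_anneal_cpp(w, gamma_pos, gamma_neg, as.integer(n_spins),
                              as.integer(seed), t_start, t_end, cooling,
                              as.integer(sweeps_per_temp),
                              as.integer(restarts))
  part <- canonicalize(setNames(res$assignment, rownames(w)))
  part$hamiltonian <- res$hamiltonian
  part
}

# stable string key for counting canonical partitions
partition_key <- function(partition) {
  paste(partition$assignment, collapse = "-")
}

#' Modal partition over repeated Spinglass runs
#'
#' Repeats [spinglass_partition()] with seeds `seed_base`,
#' `seed_base + 1`, ..., counts canonical partitions, and reports the most
#' frequent one. Ties are broken by lower mean Hamiltonian, then
#' lexicographically by assignment.
#'
#' @inheritParams spinglass_partition
#' @param n_runs Number of repetitions (default 1000).
#' @param seed_base First seed.
#' @return An `ef_modal_partition`: `modal` (an `ef_partition`), `frequency`
#'   (modal count / runs), `n_runs`, `distribution` (tibble of canonical
#'   keys, counts, mean energies).
#' @export
modal_partition <- function(network, n_runs = 1000L, seed_base = 1L,
                            gamma_pos = 1, gamma_neg = 1, n_spins = NULL,
                            t_start = 1, t_end = 0.01, cooling = 0.99,
                            sweeps_per_temp = 1L, restarts = 12L) {
  runs <- purrr::map(seq_len(n_runs) - 1L, function(i) {
    spinglass_partition(network, gamma_pos = gamma_pos, gamma_neg = gamma_neg,
                        n_spins = n_spins, seed = seed_base + i,
                        t_start = t_start, t_end = t_end, cooling = cooling,
                        sweeps_per_temp = sweeps_per_temp, restarts = restarts)
  })
  keys <- vapply(runs, partition_key, character(1))
  energies <- vapply(runs, function(r) r$hamiltonian, numeric(1))
  dist <- tibble::tibble(key = keys, hamiltonian = energies) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(count = dplyr::n(),
                     mean_hamiltonian = mean(.data$hamiltonian),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$mean_hamiltonian,
                   .data$key)
  modal_key <- dist$key[1L]
  modal <- runs[[match(modal_key, keys)]]
  structure(list(
    modal = modal,
    frequency = dist$count[1L] / n_runs,
    n_runs = as.integer(n_runs),
    distribution = dist
  ), class = "ef_modal_partition")
}

#' @export
print.ef_modal_partition <- function(x, ...) {
  cat(sprintf("<ef_modal_partition> modal grouping in %.1f%% of %d runs\n",
              100 * x$frequency, x$n_runs))
  print(x$modal)
  invisible(x)
}

#' Serialize a modal partition as JSON
#'
#' @param x An `ef_modal_partition` (or `ef_partition`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(x, path) {
  payload <- if (inherits(x, "ef_modal_partition")) {
    list(assignment = as.list(x$modal$assignment),
         n_communities = x$modal$n_communities,
         hamiltonian = x$modal$hamiltonian,
         frequency = x$frequency,
         n_runs = x$n_runs,
         distribution = x$distribution)
  } else {
    list(assignment = as.list(x$assignment),
         n_communities = x$n_communities,
         hamiltonian = x$hamiltonian)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
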