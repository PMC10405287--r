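# Network stability across cohorts and timepoints: Fisher-transformed
# edge-weight correlations, the 12 x 12 correlation matrix, and the one-way
# ANOVA with Tukey post-hocs on within-cohort correlation sets.

#' Fisher z-transform
#'
#' `z = atanh(r)`, the variance-stabilizing transform applied to partial
#' correlations before they are compared or averaged.
#'
#' @param r Correlation(s) strictly inside (-1, 1).
#' @return Numeric vector of z values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    abort("Fisher transform requires |r| < 1", class = "efnet_stability_error")
  }
  atanh(r)
}

#' Correlation between two networks' edge weights
#'
#' Pearson correlation of the Fisher-transformed off-diagonal edge weights
#' of two networks over the same node set, with a Fisher-method confidence
#' interval on the number of edges.
#'
#' @param net_a,net_b `ef_network` objects (or symmetric matrices) with
#'   identical node labels in identical order.
#' @param conf_level CI coverage (default 0.95).
#' @return A tibble row: `r`, `ci_low`, `ci_high`, `n_edges`.
#' @export
network_correlation <- function(net_a, net_b, conf_level = 0.95) {
  wa <- if (inherits(net_a, "ef_network")) net_a$pcor else as.matrix(net_a)
  wb <- if (inherits(net_b, "ef_network")) net_b$pcor else as.matrix(net_b)
  la <- rownames(wa) %||% colnames(wa)
  lb <- rownames(wb) %||% colnames(wb)
  if (!identical(dim(wa), dim(wb)) ||
      (!is.null(la) && !is.null(lb) && !identical(la, lb))) {
    abort("networks must share the same node labels in the same order",
          class = "efnet_stability_error")
  }
  ea <- fisher_z(wa[upper.tri(wa)])
  eb <- fisher_z(wb[upper.tri(wb)])
  r <- cor(ea, eb)
  n <- length(ea)
  zcrit <- qnorm(1 - (1 - conf_level) / 2)
  ci <- tanh(atanh(r) + c(-1, 1) * zcrit / sqrt(n - 3))
  tibble::tibble(r = r, ci_low = ci[1L], ci_high = ci[2L], n_edges = n)
}

# indices of the 6 within-cohort timepoint pairs inside one 4x4 block
within_block_pairs <- function(block_idx) {
  pairs <- which(upper.tri(diag(length(block_idx))), arr.ind = TRUE)
  cbind(block_idx[pairs[, 1L]], block_idx[pairs[, 2L]])
}

#' One-way ANOVA on within-cohort network correlations
#'
#' Extracts, for each cohort, the between-timepoint correlations of its own
#' networks (the 4-choose-2 = 6 upper-triangle cells of the cohort's
#' diagonal block), Fisher-transforms them, and runs a fixed-effects one-way
#' ANOVA across cohorts (df 2, 15 in the default 3 x 4 design) with
#' `eta_squared = SSB / (SSB + SSW)`. This asks whether network organization
#' is less stable over time in some cohorts than in others.
#'
#' @param corr_matrix Square correlation matrix of networks (e.g. 12 x 12
#'   ordered cohort-by-timepoint).
#' @param cohort_blocks Named list of row/column index vectors, one per
#'   cohort.
#' @return A list: `anova` (tibble: `f_statistic`, `df1`, `df2`, `p_value`,
#'   `eta_squared`), `groups` (long tibble of Fisher-z values), `tukey`
#'   (tibble from [tukey_hsd()]).
#' @export
within_cohort_anova <- function(corr_matrix, cohort_blocks) {
  corr_matrix <- as.matrix(corr_matrix)
  vals <- purrr::imap(cohort_blocks, function(idx, nm) {
    pr <- within_block_pairs(idx)
    r <- corr_matrix[pr]
    if (any(is.na(r))) {
      abort("missing cells in within-cohort correlation block",
            class = "efnet_stability_error")
    }
    tibble::tibble(cohort = nm, z = fisher_z(r))
  })
  groups <- dplyr::bind_rows(vals)
  groups$cohort <- factor(groups$cohort, levels = names(cohort_blocks))
  if (nrow(groups) - length(cohort_blocks) < 1L) {
    warn(paste("not enough within-cohort correlation pairs for an ANOVA;",
               "need at least two timepoint pairs per cohort"))
    return(list(
      anova = tibble::tibble(f_statistic = NA_real_,
                             df1 = length(cohort_blocks) - 1L,
                             df2 = nrow(groups) - length(cohort_blocks),
                             p_value = NA_real_, eta_squared = NA_real_),
      groups = groups,
      tukey = tibble::tibble(comparison = character(),
                             difference = numeric(), ci_low = numeric(),
                             ci_high = numeric(), p_value = numeric())))
  }
  fit <- aov(z ~ cohort, data = groups)
  sm <- summary(fit)[[1L]]
  ssb <- sm$`Sum Sq`[1L]
  ssw <- sm$`Sum Sq`[2L]
  anova_tbl <- tibble::tibble(
    f_statistic = sm$`F value`[1L],
    df1 = sm$Df[1L],
    df2 = sm$Df[2L],
    p_value = sm$`Pr(>F)`[1L],
    eta_squared = ssb / (ssb + ssw)
  )
  list(anova = anova_tbl,
       groups = groups,
       tukey = tukey_hsd(split(groups$z, groups$cohort)))
}

#' Tukey honestly-significant-difference comparisons
#'
#' Pairwise mean differences with studentized-range confidence intervals
#' and p-values, computed on the supplied (Fisher-z) values via
#' [stats::TukeyHSD()].
#'
#' @param groups Named list of numeric vectors, one per group.
#' @param conf_level CI coverage (default 0.95).
#' @return A tibble: `comparison`, `difference`, `ci_low`, `ci_high`,
#'   `p_value`.
#' @export
tukey_hsd <- function(groups, conf_level = 0.95) {
  d <- tibble::tibble(
    g = factor(rep(names(groups), lengths(groups)), levels = names(groups)),
    y = unlist(groups, use.names = FALSE))
  tk <- TukeyHSD(aov(y ~ g, data = d), conf.level = conf_level)$g
  tibble::tibble(
    comparison = rownames(tk),
    difference = unname(tk[, "diff"]),
    ci_low = unname(tk[, "lwr"]),
    ci_high = unname(tk[, "upr"]),
    p_value = unname(tk[, "p adj"])
  )
}

#' Network-stability analysis across all strata
#'
#' Correlates the Fisher-transformed edge weights of every pair of
#' cohort-by-timepoint networks, assembles the full correlation matrix with
#' confidence intervals, and tests whether within-cohort (between-timepoint)
#' stability differs across cohorts with a one-way ANOVA and Tukey
#' post-hocs.
#'
#' @param networks Named list of `ef_network` objects; names like
#'   `"G34_t1"` (cohort, then timepoint) determine the ordering and the
#'   cohort blocks.
#' @return An `ef_stability`: `network_ids`, `corr_matrix`, `ci_low`,
#'   `ci_high`, `within` (long tibble of within-cohort z values), `anova`,
#'   `tukey`.
#' @export
network_stability <- function(networks) {
  ids <- names(networks)
  if (is.null(ids)) {
    abort("networks list must be named (e.g. G34_t1)",
          class = "efnet_stability_error")
  }
  k <- length(networks)
  cm <- diag(k)
  lo <- diag(k)
  hi <- diag(k)
  dimnames(cm) <- dimnames(lo) <- dimnames(hi) <- list(ids, ids)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      nc <- network_correlation(networks[[i]], networks[[j]])
      cm[i, j] <- cm[j, i] <- nc$r
      lo[i, j] <- lo[j, i] <- nc$ci_low
      hi[i, j] <- hi[j, i] <- nc$ci_high
    }
  }
  cohorts <- sub("_t\\d+$", "", ids)
  blocks <- split(seq_len(k), factor(cohorts, levels = unique(cohorts)))
  res <- within_cohort_anova(cm, blocks)
  structure(list(
    network_ids = ids,
    corr_matrix = cm,
    ci_low = lo,
    ci_high = hi,
    within = res$groups,
    anova = res$anova,
    tukey = res$tukey
  ), class = "ef_stability")
}

#' @export
print.ef_stability <- function(x, ...) {
  cat(sprintf("<ef_stability> %d networks\n", length(x$network_ids)))
  a <- x$anova
  cat(sprintf("  ANOVA: F(%d, %d) = %.2f, p = %.4g, eta^2 = %.2f\n",
              a$df1, a$df2, a$f_statistic, a$p_value, a$eta_squared))
  for (i in seq_len(nrow(x$tukey))) {
    cat(sprintf("  Tukey %s: diff = %.2f [%.2f, %.2f], p = %.3g\n",
                x$tukey$comparison[i], x$tukey$difference[i],
                x$tukey$ci_low[i], x$tukey$ci_high[i], x$tukey$p_value[i]))
  }
  invisible(x)
}

#' Reference network-correlation matrix (published study)
#'
#' The printed correlations (with 95% CIs) of network edge weights between
#' the 12 cohort-by-timepoint networks of a published two-year accelerated
#' longitudinal study of executive functions in grades 3-8, bundled as a
#' regression fixture: re-running [within_cohort_anova()] on it reproduces
#' the study's stability ANOVA (F(2,15), eta-squared 0.60) and Tukey
#' contrasts from rounded table values.
#'
#' @return A list: `corr_matrix` (12 x 12, labels `G34_t1` ... `G78_t4`),
#'   `ci_low`, `ci_high`, and `blocks` (cohort index list).
#' @export
reference_network_correlations <- function() {
  path <- system.file("extdata", "reference_network_correlations.csv",
                      package = "efnet", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(c(d$network_a, d$network_b))
  k <- length(ids)
  cm <- diag(k)
  lo <- diag(k)
  hi <- diag(k)
  dimnames(cm) <- dimnames(lo) <- dimnames(hi) <- list(ids, ids)
  for (row in seq_len(nrow(d))) {
    i <- match(d$network_a[row], ids)
    j <- match(d$network_b[row], ids)
    cm[i, j] <- cm[j, i] <- d$r[row]
    lo[i, j] <- lo[j, i] <- d$ci_low[row]
    hi[i, j] <- hi[j, i] <- d$ci_high[row]
  }
  cohorts <- sub("_t\\d+$", "", ids)
  list(corr_matrix = cm, ci_low = lo, ci_high = hi,
       blocks = split(seq_len(k), factor(cohorts, levels = unique(cohorts))))
}

#' Write the stability matrix as CSV with bracketed CIs
#'
#' @param stability An `ef_stability`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stability_matrix <- function(stability, path) {
  cm <- stability$corr_matrix
  lo <- stability$ci_low
  hi <- stability$ci_high
  out <- matrix("", nrow(cm), ncol(cm), dimnames = dimnames(cm))
  for (i in seq_len(nrow(cm))) {
    for (j in seq_len(ncol(cm))) {
      out[i, j] <- if (i == j) "1.00" else
        sprintf("%.2f [%.2f, %.2f]", cm[i, j], lo[i, j], hi[i, j])
    }
  }
  utils::write.csv(as.data.frame(out), path)
  invisible(path)
}
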