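# Quality-control cascade: trial filter -> task inclusion -> MAD outliers ->
# Cook's-distance outliers, applied task-wise so students are never wholly
# excluded (except colorblind screening).

#' Filter unusable trials
#'
#' Drops anticipatory responses (RT strictly below 200 ms) and no-response
#' trials on tasks where a response was expected (forced-choice and simple-RT
#' tasks). Withheld responses in go/no-go tasks are meaningful (correct
#' rejections and misses) and are retained. The 200 ms boundary itself is
#' kept.
#'
#' @param trials Long trial tibble with `rt_ms` and `response_expected`.
#' @param anticipatory_ms Anticipation cutoff (default 200 ms).
#' @return The filtered tibble, with attribute `"dropped"` counting
#'   `no_response` and `anticipatory` removals.
#' @export
filter_trials <- function(trials, anticipatory_ms = 200) {
  responded <- !is.na(trials$rt_ms)
  no_resp_drop <- !responded & trials$response_expected
  antic_drop <- responded & trials$rt_ms < anticipatory_ms
  out <- trials[!(no_resp_drop | antic_drop), , drop = FALSE]
  attr(out, "dropped") <- c(no_response = sum(no_resp_drop),
                            anticipatory = sum(antic_drop))
  out
}

#' Task-level inclusion rule
#'
#' A task block is analyzable only if every condition has at least
#' `min_trials` responded trials and accuracy on the easiest condition beats
#' chance in a one-sided exact binomial test at `alpha`. Tasks without a
#' chance level (span, BRT) apply the trial-count rule only.
#'
#' @param task_trials One (student, timepoint, task) block of trials.
#' @param spec The matching [task_battery()] row.
#' @param min_trials Minimum responded trials per condition (default 5).
#' @param alpha Test level (default 0.05).
#' @return `TRUE` if the block is included.
#' @export
task_inclusion <- function(task_trials, spec, min_trials = 5L, alpha = 0.05) {
  stopifnot(nrow(spec) == 1L)
  conds <- spec$conditions[[1]]
  responded <- task_trials[!is.na(task_trials$rt_ms), ]
  if (spec$adaptive == "span") {
    return(nrow(responded) >= min_trials)
  }
  n_by_cond <- table(factor(responded$condition, levels = conds$condition))
  if (any(n_by_cond < min_trials)) {
    return(FALSE)
  }
  chance <- spec$chance
  if (is.na(chance)) {
    return(TRUE)
  }
  easiest <- conds$condition[conds$easiest][1]
  if (spec$response_type == "gonogo") {
    # accuracy over all trials of the (single-condition) easiest block,
    # withholds included: chance is a coin flip per trial
    block <- task_trials[task_trials$condition == easiest, ]
    x <- sum(block$correct)
    n <- nrow(block)
  } else {
    block <- responded[responded$condition == easiest, ]
    x <- sum(block$correct)
    n <- nrow(block)
  }
  if (n == 0L) {
    return(FALSE)
  }
  binom.test(x, n, p = chance, alternative = "greater")$p.value < alpha
}

#' Robust outlier flags from the 3-MAD rule
#'
#' Flags values farther than `k` scaled median absolute deviations (the
#' 1.4826 consistency constant) from the median. If the MAD degenerates to
#' zero, any value unequal to the median is flagged. Invariant under affine
#' transforms of the value scale.
#'
#' @param values Numeric vector (one cohort x timepoint x task cell set);
#'   `NA`s are never flagged.
#' @param k Multiplier (default 3).
#' @return Logical vector the length of `values`.
#' @export
mad_outliers <- function(values, k = 3) {
  med <- median(values, na.rm = TRUE)
  s <- mad(values, na.rm = TRUE) # 1.4826 * median(|x - med|)
  flag <- if (is.na(s) || s == 0) {
    values != med
  } else {
    abs(values - med) > k * s
  }
  flag & !is.na(values)
}

#' Influence flags from Cook's distance
#'
#' Fits ordinary least squares of the metric on the covariate set (by
#' default BRT, age and months since first assessment) and flags
#' observations with Cook's distance above `threshold`.
#'
#' @param metric Numeric response vector.
#' @param covariates Data frame of covariates (rows aligned with `metric`).
#' @param threshold Flag cutoff (default 1).
#' @return Logical vector the length of `metric`; rows with missing values
#'   are unflagged.
#' @export
cooks_outliers <- function(metric, covariates, threshold = 1) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(metric))
  d <- cbind(data.frame(.y = metric), covariates)
  ok <- complete.cases(d)
  flag <- rep(FALSE, length(metric))
  if (sum(ok) <= ncol(covariates) + 1L) {
    return(flag)
  }
  fit <- lm(.y ~ ., data = d[ok, , drop = FALSE])
  if (fit$rank < ncol(covariates) + 1L) {
    abort("rank-deficient covariate design in Cook's-distance screen",
          class = "efnet_qc_error")
  }
  cd <- cooks.distance(fit)
  flag[ok] <- !is.na(cd) & cd > threshold
  flag
}

#' Apply the full QC cascade
#'
#' Order of operations: red-green colorblind students are removed entirely;
#' trial-level filtering ([filter_trials()]) and the task-inclusion rule
#' ([task_inclusion()]) blank task cells without enough clean, above-chance
#' data; then 3-MAD flags within each cohort x timepoint x task; then
#' Cook's-distance flags from the metric ~ BRT + age + time regression.
#' Flags other than colorblindness blank only the offending metric cell.
#'
#' @param metric_table Metric tibble from [build_metric_table()] (built from
#'   already trial-filtered data, or raw — trials are re-filtered here for
#'   the audit counts).
#' @param trials Long trial tibble backing `metric_table`; pass `NULL` to
#'   skip the trial-dependent steps (inclusion rule, colorblind screen uses
#'   `colorblind` column if present).
#' @param battery [task_battery()] rows for the inclusion rule.
#' @param population Optional [simulate_population()] tibble supplying the
#'   `colorblind` flag per student.
#' @param cooks_threshold,mad_k Cutoffs for the two outlier screens.
#' @return A list with `table` (cleaned metric tibble) and `report` (an
#'   `ef_qc_report`: per-cell flag tibble plus drop counts and the exclusion
#'   fraction).
#' @export
apply_qc <- function(metric_table, trials = NULL, battery = NULL,
                     population = NULL, cooks_threshold = 1, mad_k = 3) {
  col_of <- task_metric_column()
  metric_cols <- unname(col_of)
  flags <- tibble::tibble(
    student_id = character(), timepoint = integer(), column = character(),
    flag = character())
  dropped <- c(no_response = 0L, anticipatory = 0L)

  # 1. colorblind exclusion (whole student)
  cb_ids <- character()
  if (!is.null(population) && "colorblind" %in% names(population)) {
    cb_ids <- population$student_id[population$colorblind]
  } else if ("colorblind" %in% names(metric_table)) {
    cb_ids <- unique(metric_table$student_id[metric_table$colorblind])
  }
  if (length(cb_ids)) {
    cb_rows <- metric_table$student_id %in% cb_ids
    flags <- dplyr::bind_rows(flags, tibble::tibble(
      student_id = metric_table$student_id[cb_rows],
      timepoint = metric_table$timepoint[cb_rows],
      column = "ALL", flag = "colorblind_excluded"))
    metric_table <- metric_table[!cb_rows, , drop = FALSE]
  }

  # 2. trial filter + task-inclusion rule
  if (!is.null(trials)) {
    trials <- trials[!trials$student_id %in% cb_ids, , drop = FALSE]
    filtered <- filter_trials(trials)
    dropped <- attr(filtered, "dropped")
    battery <- battery %||% task_battery(ef_config())
    blocks <- filtered |>
      dplyr::group_by(.data$student_id, .data$timepoint, .data$task) |>
      tidyr::nest() |>
      dplyr::ungroup()
    blocks$included <- purrr::map2_lgl(blocks$task, blocks$data, function(tk, d) {
      task_inclusion(d, battery[battery$task == tk, ])
    })
    bad <- blocks[!blocks$included, c("student_id", "timepoint", "task")]
    if (nrow(bad)) {
      bad$column <- unname(col_of[bad$task])
      for (i in seq_len(nrow(bad))) {
        hit <- metric_table$student_id == bad$student_id[i] &
          metric_table$timepoint == bad$timepoint[i]
        metric_table[[bad$column[i]]][hit] <- NA_real_
      }
      flags <- dplyr::bind_rows(flags, tibble::tibble(
        student_id = bad$student_id, timepoint = as.integer(bad$timepoint),
        column = bad$column, flag = "too_few_trials_or_at_chance"))
    }
  }

  # 3 & 4. MAD then Cook's-distance screens within cohort x timepoint x
  # task, iterated to a fixed point so the whole cascade is a projection:
  # re-applying QC to its own output changes nothing
  covar_cols <- intersect(c("brt_mean_rt", "age_months"),
                          names(metric_table))
  grp <- interaction(metric_table$cohort, metric_table$timepoint, drop = TRUE)
  repeat {
    new_flags <- FALSE
    for (col in intersect(metric_cols, names(metric_table))) {
      for (g in levels(grp)) {
        idx <- which(grp == g)
        f <- mad_outliers(metric_table[[col]][idx], k = mad_k)
        if (any(f)) {
          new_flags <- TRUE
          flags <- dplyr::bind_rows(flags, tibble::tibble(
            student_id = metric_table$student_id[idx[f]],
            timepoint = as.integer(metric_table$timepoint[idx[f]]),
            column = col, flag = "mad_outlier"))
          metric_table[[col]][idx[f]] <- NA_real_
        }
      }
    }
    for (col in setdiff(intersect(metric_cols, names(metric_table)),
                        "brt_mean_rt")) {
      for (g in levels(grp)) {
        idx <- which(grp == g)
        covs <- metric_table[idx, covar_cols, drop = FALSE]
        f <- cooks_outliers(metric_table[[col]][idx], covs,
                            threshold = cooks_threshold)
        if (any(f)) {
          new_flags <- TRUE
          flags <- dplyr::bind_rows(flags, tibble::tibble(
            student_id = metric_table$student_id[idx[f]],
            timepoint = as.integer(metric_table$timepoint[idx[f]]),
            column = col, flag = "cooks_outlier"))
          metric_table[[col]][idx[f]] <- NA_real_
        }
      }
    }
    if (!new_flags) break
  }

  n_cells <- sum(!is.na(as.matrix(
    metric_table[, intersect(metric_cols, names(metric_table))]))) +
    sum(flags$flag %in% c("mad_outlier", "cooks_outlier",
                          "too_few_trials_or_at_chance"))
  n_flagged <- sum(flags$flag %in% c("mad_outlier", "cooks_outlier",
                                     "too_few_trials_or_at_chance"))
  report <- structure(list(
    flags = flags,
    trials_dropped = dropped,
    excluded_fraction = if (n_cells > 0) n_flagged / n_cells else 0
  ), class = "ef_qc_report")
  list(table = metric_table, report = report)
}

#' @export
print.ef_qc_report <- function(x, ...) {
  cat("<ef_qc_report>\n")
  cat(sprintf("  trials dropped: %d no-response, %d anticipatory\n",
              x$trials_dropped[["no_response"]],
              x$trials_dropped[["anticipatory"]]))
  if (nrow(x$flags)) {
    tab <- table(x$flags$flag)
    for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  }
  cat(sprintf("  task-level exclusion fraction: %.2f%%\n",
              100 * x$excluded_fraction))
  invisible(x)
}

#' Serialize a QC report
#'
#' @param report An `ef_qc_report` from [apply_qc()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(list(
    trials_dropped = as.list(report$trials_dropped),
    excluded_fraction = report$excluded_fraction,
    flags = report$flags
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
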