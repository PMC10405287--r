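# End-to-end orchestration: simulate -> metrics -> QC -> adjust -> networks
# -> communities -> stability -> CFA, with serialized artifacts.

#' Run the full analysis pipeline
#'
#' Executes every stage on synthetic data and writes all artifacts to
#' `out_dir`: `trials.csv`, `metrics.csv`, `qc_report.json`,
#' `adjusted.csv`, one network JSON and edge CSV per cohort x timepoint,
#' `communities.json`, `stability.json`, `stability_matrix.csv`,
#' `cfa_grid.csv` and a `manifest.json` (config hash, seed, package
#' version). A rerun with the same config reproduces identical numeric
#' outputs. Trial-level simulation feeds the metric/QC/feedback stages; the
#' network, community and CFA stages run on metric-level data generated
#' from the configured factor structures (`metric_n` rows per stratum), the
#' scale at which those analyses are benchmarked.
#'
#' @param config An [ef_config()] or a YAML path readable by
#'   [read_ef_config()].
#' @param out_dir Output directory (created if needed).
#' @param metric_n Rows per stratum for the metric-level stages (default
#'   400).
#' @param n_community_runs Spinglass repetitions per network (default 1000).
#' @param trial_stages Run the trial-level stages (simulation, metrics, QC,
#'   feedback model)? Default `TRUE`; disable for metric-only studies.
#' @return Invisibly, a list with every in-memory stage result.
#' @export
run_pipeline <- function(config, out_dir, metric_n = 400L,
                         n_community_runs = 1000L, trial_stages = TRUE) {
  if (is.character(config)) {
    config <- read_ef_config(config)
  }
  stopifnot(inherits(config, "ef_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), class = "efnet_pipeline_error")
    })
  }
  results <- list(config = config)

  if (trial_stages) {
    results$population <- stage("simulate", simulate_population(config))
    results$trials <- stage("simulate", {
      tr <- simulate_trials(config, results$population)
      apply_missingness(tr, config)
    })
    utils::write.csv(results$trials, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
    results$metrics <- stage("metrics", build_metric_table(results$trials))
    utils::write.csv(results$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    qc <- stage("qc", apply_qc(results$metrics, results$trials,
                               battery = task_battery(config),
                               population = results$population))
    results$qc <- qc
    write_qc_report(qc$report, file.path(out_dir, "qc_report.json"))
    results$feedback_model <- stage("feedback", {
      feedback_rate_model(feedback_long(qc$table),
                          seed = fan_seed(config$seed, "feedback_boot"))
    })
    jsonlite::write_json(results$feedback_model,
                         file.path(out_dir, "feedback_model.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  study <- stage("adjust", {
    s <- generate_metric_study(config, n = metric_n)
    adj <- residualize_on_brt(s)
    attr(adj, "structures") <- attr(s, "structures")
    adj
  })
  results$adjusted <- study
  utils::write.csv(study, file.path(out_dir, "adjusted.csv"),
                   row.names = FALSE)

  grid <- tidyr::expand_grid(cohort = ef_cohorts(),
                             timepoint = seq_len(config$n_timepoints))
  ids <- sprintf("%s_t%d", grid$cohort, grid$timepoint)
  results$networks <- stage("network", {
    nets <- purrr::pmap(grid, function(cohort, timepoint) {
      estimate_network(study, cohort, timepoint)
    })
    setNames(nets, ids)
  })
  for (id in ids) {
    write_network(results$networks[[id]],
                  file.path(out_dir, sprintf("network_%s.json", id)))
    utils::write.csv(edge_list(results$networks[[id]]),
                     file.path(out_dir, sprintf("edges_%s.csv", id)),
                     row.names = FALSE)
  }

  results$communities <- stage("communities", {
    purrr::imap(results$networks, function(net, id) {
      modal_partition(net, n_runs = n_community_runs,
                      seed_base = fan_seed(config$seed, "communities",
                                           counter = match(id, ids) * 100000L))
    })
  })
  jsonlite::write_json(
    purrr::map(results$communities, function(m) {
      list(assignment = as.list(m$modal$assignment),
           n_communities = m$modal$n_communities,
           frequency = m$frequency, n_runs = m$n_runs)
    }),
    file.path(out_dir, "communities.json"), auto_unbox = TRUE, digits = NA)

  results$stability <- stage("stability", network_stability(results$networks))
  jsonlite::write_json(list(
    anova = results$stability$anova,
    tukey = results$stability$tukey,
    corr_matrix = unname(as.data.frame(results$stability$corr_matrix))
  ), file.path(out_dir, "stability.json"), auto_unbox = TRUE, digits = NA)
  write_stability_matrix(results$stability,
                         file.path(out_dir, "stability_matrix.csv"))

  results$cfa <- stage("cfa", {
    purrr::pmap(grid, function(cohort, timepoint) {
      d <- study[study$cohort == cohort & study$timepoint == timepoint, ]
      fm <- fiml_moments(as.matrix(d[, ef_metric_columns()]))
      fits <- fit_cfa_battery(fm$cov, fm$n)
      sel <- model_selection_report(fits)
      list(cohort = cohort, timepoint = timepoint, fits = fits,
           selection = sel)
    })
  })
  cfa_grid <- dplyr::bind_rows(purrr::map(results$cfa, function(x) {
    dplyr::mutate(x$selection$comparisons, cohort = x$cohort,
                  timepoint = x$timepoint, selected = x$selection$selected,
                  .before = 1L)
  }))
  utils::write.csv(cfa_grid, file.path(out_dir, "cfa_grid.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("efnet")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    metric_n = metric_n,
    n_community_runs = n_community_runs,
    trial_stages = trial_stages,
    artifacts = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_ef_config(config, file.path(out_dir, "config.yaml"))
  invisible(results)
}

#' Ingest an external long-format metric table
#'
#' Optional adapter mapping a deposited long-format CSV onto the package's
#' metric-table schema. Validates required columns and types; extra columns
#' are dropped with a warning. No analysis stage requires this — the
#' pipeline is self-contained on synthetic data.
#'
#' @param table_path CSV path.
#' @param required Required column names (defaults to the session keys, BRT
#'   and the 8 metric columns).
#' @return A metric tibble.
#' @export
ingest_external <- function(table_path,
                            required = c("student_id", "cohort", "timepoint",
                                         "brt_mean_rt", ef_metric_columns())) {
  d <- tibble::as_tibble(utils::read.csv(table_path, stringsAsFactors = FALSE))
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    abort(paste("missing required columns:",
                paste(missing_cols, collapse = ", ")),
          class = "efnet_schema_error")
  }
  extra <- setdiff(names(d), c(required, "gender", "school_id", "age_months",
                               "months_since_first"))
  if (length(extra)) {
    warn(paste("ignoring unrecognized columns:", paste(extra, collapse = ", ")))
    d <- d[, setdiff(names(d), extra)]
  }
  numeric_cols <- intersect(c("brt_mean_rt", ef_metric_columns()), names(d))
  for (col in numeric_cols) {
    if (!is.numeric(d[[col]])) {
      abort(sprintf("column %s must be numeric", col),
            class = "efnet_schema_error")
    }
  }
  d$timepoint <- as.integer(d$timepoint)
  d
}
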