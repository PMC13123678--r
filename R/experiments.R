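#' Configure a simulation experiment
#'
#' Bundles the cohort, roster, model and policy settings of one simulation
#' study. Two presets are provided: [throughput_config()] (a 1000-patient
#' waiting list scheduled over 10 working days on six 390-minute daily
#' capacity streams) and [overtime_config()] (251 test patients, two rooms,
#' eight days), matching the two experiments the package reproduces.
#'
#' @param n_patients size of the waiting list to schedule.
#' @param n_train size of the disjoint synthetic cohort the duration model
#'   is trained on.
#' @param n_endoscopists,n_days,daily_block_minutes roster geometry.
#' @param budget_minutes daily operational time budget per room for
#'   overtime/earliness evaluation.
#' @param policies subset of `"fixed30-greedy"`, `"predictive-greedy"`,
#'   `"mip"`.
#' @param replications number of independent replications.
#' @param base_seed replication r uses seed `base_seed + r - 1`.
#' @param regressor,features,regressor_options duration-model settings.
#' @param nominative_fraction share of patients arriving with a designated
#'   endoscopist.
#' @param mip_node_limit,mip_time_limit,mip_gap_tol solver limits per
#'   replication. The node limit is the default working limit because it is
#'   deterministic (a wall-clock limit would break bit-reproducibility of
#'   the tables).
#' @param perfect_predictions if `TRUE`, predicted durations are set equal
#'   to actual durations (a no-prediction-error control).
#' @param marginals,durations generator settings.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_patients, n_train = 1253L,
                              n_endoscopists = 6L, n_days = 10L,
                              daily_block_minutes = DEFAULT_BUDGET_MINUTES,
                              budget_minutes = DEFAULT_BUDGET_MINUTES,
                              policies = c("fixed30-greedy",
                                           "predictive-greedy", "mip"),
                              replications = 1L, base_seed = 1L,
                              regressor = "gradient_boosted_trees",
                              features = c("procedure_type",
                                           "endoscopist_type",
                                           "respiratory", "diabetes"),
                              regressor_options = list(nrounds = 80L),
                              nominative_fraction = 0.5,
                              mip_node_limit = 1e5, mip_time_limit = Inf,
                              mip_gap_tol = 1e-6,
                              perfect_predictions = FALSE,
                              marginals = default_marginals(),
                              durations = duration_params()) {
  stopifnot(replications >= 1L,
            all(policies %in% c("fixed30-greedy", "predictive-greedy", "mip")))
  structure(as.list(environment()), class = "experiment_config")
}

#' @rdname experiment_config
#' @param ... overrides passed to [experiment_config()].
#' @export
throughput_config <- function(...) {
  defaults <- list(n_patients = 1000L, n_train = 1253L, n_endoscopists = 6L,
                   n_days = 10L)
  do.call(experiment_config, utils::modifyList(defaults, list(...)))
}

#' @rdname experiment_config
#' @export
overtime_config <- function(...) {
  defaults <- list(n_patients = 251L, n_train = 1002L, n_endoscopists = 2L,
                   n_days = 8L)
  do.call(experiment_config, utils::modifyList(defaults, list(...)))
}

# One replication: generate roster + cohorts, train the model, run every
# policy on identical inputs, and return one metrics_report per policy.
run_replication <- function(config, seed) {
  prov <- generate_roster(roster_spec(
    config$n_endoscopists, config$n_days, config$daily_block_minutes,
    seed = substream_seed(seed, "roster")))
  cohort <- generate_cohort(cohort_spec(
    config$n_patients, marginals = config$marginals,
    duration_params = config$durations,
    nominative_fraction = config$nominative_fraction,
    seed = substream_seed(seed, "cohort")), roster = prov$roster)
  if (config$perfect_predictions) {
    cohort$predicted_minutes <- cohort$actual_minutes
  } else {
    train <- generate_cohort(cohort_spec(
      config$n_train, marginals = config$marginals,
      duration_params = config$durations,
      seed = substream_seed(seed, "train")))
    model <- do.call(train_duration_model,
                     c(list(train = clean_cohort(train),
                            regressor_spec = config$regressor,
                            features = config$features,
                            seed = substream_seed(seed, "model")),
                       config$regressor_options))
    cohort$predicted_minutes <- predict_durations(model, cohort)
  }
  input_hash <- rlang::hash(list(cohort, prov$roster, prov$calendar))

  schedules <- list()
  need_pred_greedy <- any(c("predictive-greedy", "mip") %in% config$policies)
  if ("fixed30-greedy" %in% config$policies) {
    wl <- sort_waiting_list(cohort, "fixed")
    schedules[["fixed30-greedy"]] <- schedule_greedy(wl, prov$roster,
                                                     prov$calendar)
  }
  pred_greedy <- NULL
  if (need_pred_greedy) {
    wl <- sort_waiting_list(cohort, "predictive")
    pred_greedy <- schedule_greedy(wl, prov$roster, prov$calendar)
  }
  if ("predictive-greedy" %in% config$policies) {
    schedules[["predictive-greedy"]] <- pred_greedy
  }
  if ("mip" %in% config$policies) {
    mc <- cohort
    mc$appointment_minutes <- appointment_duration(mc$predicted_minutes,
                                                   "predictive")
    inst <- build_instance(mc, prov$roster, prov$calendar)
    sol <- solve_mip(inst, gap_tol = config$mip_gap_tol,
                     node_limit = config$mip_node_limit,
                     time_limit = config$mip_time_limit,
                     warm_start = pred_greedy)
    schedules[["mip"]] <- sequence_within_day(sol, inst, mc)
  }
  reports <- lapply(config$policies, function(pol) {
    rep <- build_report(schedules[[pol]], cohort, prov$calendar,
                        budget_minutes = config$budget_minutes)
    rep$input_hash <- input_hash
    rep
  })
  names(reports) <- config$policies
  list(reports = reports, schedules = schedules, cohort = cohort,
       roster = prov$roster, calendar = prov$calendar)
}

report_row <- function(report, replication) {
  row <- data.frame(
    replication = replication, policy = report$policy,
    n_scheduled = report$n_scheduled_total,
    n_unscheduled = report$n_unscheduled,
    avg_late_days = report$avg_late_days_total,
    avg_wait_days = report$avg_wait_days_total,
    total_overtime = report$total_overtime_minutes,
    avg_overtime_day_room = report$avg_overtime_per_day_room,
    total_earliness = report$total_earliness_minutes,
    avg_earliness_day_room = report$avg_earliness_per_day_room,
    input_hash = report$input_hash %||% NA_character_,
    stringsAsFactors = FALSE)
  for (cl in PRIORITY_LEVELS) {
    row[[paste0("n_", cl)]] <- report$n_scheduled_by_class[[cl]]
    row[[paste0("avg_late_", cl)]] <- report$avg_late_days_by_class[[cl]]
  }
  row
}

run_experiment <- function(config) {
  rows <- list()
  for (r in seq_len(config$replications)) {
    rep_out <- run_replication(config, config$base_seed + r - 1L)
    rows <- c(rows, lapply(rep_out$reports, report_row, replication = r))
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  num_cols <- setdiff(names(rows)[vapply(rows, is.numeric, logical(1))],
                      "replication")
  agg_mean <- aggregate(rows[num_cols], by = list(policy = rows$policy), mean)
  agg_se <- aggregate(rows[num_cols], by = list(policy = rows$policy),
                      function(v) sd(v) / sqrt(length(v)))
  names(agg_se)[-1] <- paste0(names(agg_se)[-1], "_se")
  summary <- merge(agg_mean, agg_se, by = "policy", sort = FALSE)
  summary <- summary[match(config$policies, summary$policy), , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(rows = rows, summary = summary, config = config),
            class = "comparison_table")
}

#' Throughput experiment: how many patients fit in the horizon?
#'
#' For each replication, generates a waiting list, trains the duration
#' model on a disjoint synthetic cohort, and runs every configured policy
#' on identical inputs (same cohort, predictions, roster and calendar,
#' asserted by an input hash carried in every report row). Reports
#' scheduled counts and lateness overall and per priority class.
#'
#' @param config an [experiment_config()]; defaults to
#'   [throughput_config()].
#' @return A `comparison_table`: per-replication rows plus
#'   across-replication means and standard errors.
#' @export
run_experiment_throughput <- function(config = throughput_config()) {
  run_experiment(config)
}

#' Overtime/earliness experiment: does prediction error overbook rooms?
#'
#' Schedules are built on planned minutes (flat slots or prediction plus
#' buffer) but evaluated on realized appointment minutes, so per-room-day
#' overtime and earliness expose the cost of prediction error.
#'
#' @param config an [experiment_config()]; defaults to [overtime_config()].
#' @return A `comparison_table`.
#' @export
run_experiment_overtime <- function(config = overtime_config()) {
  run_experiment(config)
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("<comparison_table> %d policies x %d replication(s)\n",
              length(unique(x$rows$policy)),
              max(x$rows$replication)))
  cols <- c("policy", "n_scheduled", "avg_late_days",
            "avg_overtime_day_room", "avg_earliness_day_room")
  print(x$summary[, intersect(cols, names(x$summary)), drop = FALSE],
        digits = 4)
  invisible(x)
}

#' Write a comparison table to disk
#'
#' Emits the per-replication rows and the across-replication summary as
#' CSV, plus two human-readable text layouts: a throughput table (counts
#' and average late days, overall and per priority class) and a
#' utilization table (total and per-day-per-room overtime and earliness).
#' The base seed and configuration are echoed in header comments.
#'
#' @param table a `comparison_table`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(table, dir, prefix = "experiment") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- table$config
  hdr <- c(sprintf("# base_seed: %s  replications: %s",
                   cfg$base_seed, cfg$replications),
           sprintf("# cohort: n=%s  roster: %s endoscopists x %s days x %s min",
                   cfg$n_patients, cfg$n_endoscopists, cfg$n_days,
                   cfg$daily_block_minutes))
  paths <- c(rows = file.path(dir, paste0(prefix, "_replications.csv")),
             summary = file.path(dir, paste0(prefix, "_summary.csv")),
             throughput = file.path(dir, paste0(prefix, "_throughput.txt")),
             utilization = file.path(dir, paste0(prefix, "_utilization.txt")))
  for (nm in c("rows", "summary")) {
    con <- file(paths[[nm]], "w")
    writeLines(hdr, con)
    write.csv(table[[nm]], con, row.names = FALSE)
    close(con)
  }
  s <- table$summary
  fmt_block <- function(cols, digits = 2) {
    df <- s[, c("policy", cols), drop = FALSE]
    df[-1] <- lapply(df[-1], round, digits)
    capture.output(print(df, row.names = FALSE))
  }
  tp_cols <- c("n_scheduled", "avg_late_days",
               as.vector(rbind(paste0("n_", PRIORITY_LEVELS),
                               paste0("avg_late_", PRIORITY_LEVELS))))
  writeLines(c(hdr, "", "Scheduled patients and average late days (overall, then per priority class)",
               fmt_block(tp_cols)), paths[["throughput"]])
  ut_cols <- c("n_scheduled", "avg_late_days", "total_overtime",
               "avg_overtime_day_room", "total_earliness",
               "avg_earliness_day_room")
  writeLines(c(hdr, "", "Overtime and earliness against the daily time budget",
               fmt_block(ut_cols)), paths[["utilization"]])
  invisible(paths)
}
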