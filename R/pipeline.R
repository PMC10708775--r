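#' Run the full monitoring pipeline on a synthetic crowd
#'
#' simulate -> window -> assess -> classify -> correlate -> alert ->
#' evaluate, fully seeded. The forest is trained on the intervals that
#' overlap ground-truth events (artifact = fluctuation, sustained drift =
#' saturation); when fewer than two event classes exist in a run, a
#' self-supervised fallback labels intervals by the abrupt-change flag
#' (saturation when the window mean leaves the clinical band, fluctuation
#' otherwise). A person is judged infected when at least half of their
#' assessed intervals carry abnormal status.
#'
#' @param config A [simulation_config()].
#' @param calib A [calibration_spec()]; defaults to one matched to the
#'   config's interval length.
#' @param threshold Decision threshold for [decide_status()].
#' @param k Persistence length for [decide_status()].
#' @param mitigate Apply [false_rate_mitigation()] before the status
#'   decision (default TRUE).
#' @param forest_hyper Hyperparameter overrides for [train_forest()].
#' @param out_dir Optional directory; when given, streams, logs, interval
#'   tables, alerts and the metrics report are written there.
#' @return A list with `metrics` (the five-metric report), `population`,
#'   `predictions` (per-person judgement), `intervals`, `decisions`,
#'   `alerts`, `discharge`, `events`, and the `config` used.
#' @export
run_pipeline <- function(config, calib = NULL, threshold = 1, k = 2,
                         mitigate = TRUE, forest_hyper = list(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(calib)) {
    calib <- calibration_spec(interval_length = config$interval_length)
  }
  sim <- simulate_crowd(config)
  pop <- sim$population
  pids <- pop$person_id

  # per-person assessment and features
  assess_l <- list(); feats_l <- list(); base_l <- list()
  for (pid in pids) {
    sp <- sim$stream[sim$stream$person_id == pid, , drop = FALSE]
    base_l[[pid]] <- person_baseline(pid)
    a <- tryCatch(assess_stream(sp, base_l[[pid]], calib),
                  error = function(e) NULL)
    if (is.null(a)) next
    assess_l[[pid]] <- a
    feats_l[[pid]] <- build_features(a, calib)
  }
  assessment <- do.call(rbind, c(assess_l, list(make.row.names = FALSE)))
  features <- do.call(rbind, c(feats_l, list(make.row.names = FALSE)))

  # training labels from the ground-truth event log
  truth_labels <- label_intervals(assessment, sim$events)
  have <- !is.na(truth_labels)
  model <- NULL
  if (length(unique(truth_labels[have])) >= 2) {
    model <- train_forest(features[have, , drop = FALSE], truth_labels[have],
                          hyper = forest_hyper,
                          seed = derive_seed(config$seed, 77L))
    cls <- classify_interval(model, features)
  } else {
    # self-supervised fallback: abrupt-change flag as the label
    sat <- assessment$x_sat > assessment$y_fluct
    cls <- data.frame(exists_o = as.numeric(!sat),
                      label = ifelse(sat, "saturation", "fluctuation"),
                      status = "normal", stringsAsFactors = FALSE)
  }
  classified <- cbind(assessment[, c("person_id", "interval_index",
                                     "step_start", "step_end")], cls)

  # correlation, mitigation and statuses per person
  dec_l <- list(); status_l <- list(); cc_l <- list()
  pred <- stats::setNames(rep(FALSE, length(pids)), pids)
  sigma_last <- stats::setNames(rep(0, length(pids)), pids)
  for (pid in names(assess_l)) {
    a <- assess_l[[pid]]
    f <- feats_l[[pid]]
    lab <- cls$label[classified$person_id == pid]
    series <- correlate_series(a, f, lab, calib)
    if (mitigate) series <- false_rate_mitigation(series, a$sid)
    st <- rolling_status(series, threshold, k)
    # PSId updates from normal intervals only
    b <- base_l[[pid]]
    win <- window_stream(sim$stream[sim$stream$person_id == pid, , drop = FALSE],
                         calib)
    for (i in seq_along(st)) {
      if (st[i] == "normal") b <- update_baseline(b, win[[i]], st[i])
    }
    base_l[[pid]] <- b
    dec_l[[pid]] <- cbind(person_id = pid, series, status = st,
                          stringsAsFactors = FALSE)
    status_l[[pid]] <- data.frame(
      person_id = pid, interval_index = a$interval_index, status = st,
      x_sat = a$x_sat, y_fluct = a$y_fluct, stringsAsFactors = FALSE)
    pred[pid] <- mean(st == "abnormal") >= 0.5
    sigma_last[pid] <- series$sigma_o[nrow(series)]
    # consistency-check procedure on the person's final state
    nlast <- nrow(a)
    cc_l[[pid]] <- consistency_check_procedure(
      n_consistent = sum(lab == "saturation"),
      n_inconsistent = sum(lab == "fluctuation"),
      y_over_x = series$y_over_x[nlast],
      mu_args = list(m = f$m[nlast], n = f$n[nlast], sid = a$sid[nlast],
                     exists_o = cls$exists_o[classified$person_id == pid][nlast]))
  }
  decisions <- do.call(rbind, c(dec_l, list(make.row.names = FALSE)))
  statuses <- do.call(rbind, c(status_l, list(make.row.names = FALSE)))

  # device discharge at the final interval
  dev <- do.call(rbind, lapply(names(assess_l), function(pid) {
    sp <- sim$stream[sim$stream$person_id == pid, , drop = FALSE]
    a <- assess_l[[pid]]
    data.frame(device_id = sp$device_id[1], person_id = pid,
               count_ratio = sum(a$n_out) / max(sum(a$n_in), calib$epsilon),
               sigma_o = sigma_last[pid],
               battery = sp$battery[nrow(sp)], stringsAsFactors = FALSE)
  }))
  i_max <- max(assessment$interval_index)
  discharge <- hw_discharge_probability(dev, calib, i_max)
  discharge$person_id <- dev$person_id
  omega <- stats::setNames(discharge$omega, discharge$person_id)

  # threshold-distance violations per interval, abnormal members only
  L <- config$interval_length
  viol_l <- list()
  for (t in seq_len(i_max)) {
    step_t <- min(t * L - 1, config$n_steps - 1)
    pos <- sim$movement[sim$movement$step == step_t, , drop = FALSE]
    abn_t <- stats::setNames(rep(FALSE, nrow(pos)), pos$person_id)
    st_t <- statuses[statuses$interval_index == t & statuses$status == "abnormal", ]
    abn_t[st_t$person_id[st_t$person_id %in% names(abn_t)]] <- TRUE
    v <- detect_violations(pos, unname(abn_t[pos$person_id]),
                           config$threshold_distance)
    if (nrow(v)) { v$interval_index <- t; viol_l[[length(viol_l) + 1]] <- v }
  }
  violations <- if (length(viol_l)) {
    do.call(rbind, c(viol_l, list(make.row.names = FALSE)))
  } else {
    data.frame(person_id = character(), counterpart_id = character(),
               distance = numeric(), interval_index = integer(),
               stringsAsFactors = FALSE)
  }
  alerts <- issue_recommendations(statuses, violations, discharge)

  truth <- stats::setNames(pop$infected, pop$person_id)
  judged <- names(assess_l)
  metrics <- list(
    false_rate = compute_false_rate(unname(pred[judged]),
                                    unname(truth[judged])),
    fluctuation_rate = compute_fluctuation_rate(classified, sim$events),
    data_analysis_rate = compute_data_analysis_rate(
      assessment, omega, config$n_people * config$n_steps),
    recommendation_ratio = compute_recommendation_ratio(
      alerts, sim$events, truth, assessment),
    consistency_check = compute_consistency_check(cc_l)
  )
  report <- list(
    metrics = metrics,
    balanced_accuracy = balanced_accuracy(unname(pred[judged]),
                                          unname(truth[judged])),
    population = pop,
    predictions = data.frame(person_id = judged,
                             judged_infected = unname(pred[judged]),
                             infected = unname(truth[judged]),
                             stringsAsFactors = FALSE),
    intervals = assessment,
    features = features,
    classified = classified,
    decisions = decisions,
    alerts = alerts,
    discharge = discharge,
    violations = violations,
    events = sim$events,
    stream = sim$stream,
    model = model,
    config = config,
    calib = calib
  )
  if (!is.null(out_dir)) write_run_artifacts(report, out_dir)
  report
}

#' Write a pipeline run's artifacts to a directory
#'
#' Streams as delimited text, event/decision/alert logs as JSON-lines, the
#' interval table as delimited text, and the metrics report plus a run
#' manifest (config and seed) as JSON.
#'
#' @param report Output of [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_stream(report$stream, file.path(out_dir, "stream.csv"))
  write_event_log(report$events, file.path(out_dir, "events.jsonl"))
  iv_cols <- c("person_id", "interval_index", "sid", "delta_sf", "hw_disch",
               "x_sat", "y_fluct", "norm_sid")
  utils::write.csv(report$intervals[, iv_cols],
                   file.path(out_dir, "intervals.csv"), row.names = FALSE,
                   quote = FALSE)
  dec_cols <- c("person_id", "interval_index", "branch", "exists_oi",
                "sigma_o", "status")
  write_jsonl(report$decisions[, dec_cols],
              file.path(out_dir, "decisions.jsonl"))
  write_jsonl(report$alerts, file.path(out_dir, "alerts.jsonl"))
  jsonlite::write_json(report$metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- c(unclass(report$config),
                list(package_version = as.character(
                  utils::packageVersion("crowdvitals"))))
  manifest$infected_shift <- as.list(manifest$infected_shift)
  manifest$noise_sd <- as.list(manifest$noise_sd)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
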