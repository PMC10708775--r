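#' @title Saturation-vs-fluctuation interval classification
#' @description Builds the (M, N) classifier inputs from the interval
#'   statistics, detects abrupt per-vital changes, and trains/applies a
#'   random forest that separates consistent saturation intervals (sustained
#'   out-of-range drift) from inconsistent fluctuation intervals (transient
#'   artifacts).
#' @name saturation_fluctuation_classifier
NULL

.feature_cols <- c("m", "n", "x_sat", "y_fluct", "delta_sf", "norm_sid",
                   "hw_disch")

#' Classifier inputs for a person's first interval
#'
#' First interval: `M = SId`, `N = 0`, so the input identity `M + N = SId`
#' holds by construction.
#'
#' @param sid The interval's SId score.
#' @return Named list `m`, `n`.
#' @export
build_mn_first <- function(sid) {
  list(m = sid, n = 0)
}

#' Classifier inputs for intervals in a series
#'
#' From the second interval on: `M = Norm(SId)`, `N = Y / max(X, eps)`, so
#' `M + N = Norm(SId) + Y/X`. A zero saturation count activates the epsilon
#' guard (logged).
#'
#' @param norm_sid Normalized score of the interval.
#' @param x_sat Saturation count X.
#' @param y_fluct Fluctuation value Y.
#' @param calib A [calibration_spec()].
#' @return Named list `m`, `n`.
#' @export
build_mn_series <- function(norm_sid, x_sat, y_fluct, calib) {
  if (x_sat < calib$epsilon) log_guard("mn_series_x_zero")
  list(m = norm_sid, n = y_fluct / max(x_sat, calib$epsilon))
}

#' Build the feature table for a person's interval series
#'
#' Applies [build_mn_first()] to interval 1 and [build_mn_series()] to the
#' rest, carrying the remaining interval statistics along as features.
#'
#' @param assessment Output of [assess_stream()] for one person (ordered by
#'   interval_index).
#' @param calib A [calibration_spec()].
#' @return Data frame with columns `person_id`, `interval_index`, `m`, `n`,
#'   `x_sat`, `y_fluct`, `delta_sf`, `norm_sid`, `hw_disch`.
#' @export
build_features <- function(assessment, calib) {
  a <- assessment[order(assessment$interval_index), ]
  mn <- lapply(seq_len(nrow(a)), function(i) {
    if (a$interval_index[i] == 1) {
      build_mn_first(a$sid[i])
    } else {
      build_mn_series(a$norm_sid[i], a$x_sat[i], a$y_fluct[i], calib)
    }
  })
  data.frame(
    person_id = a$person_id,
    interval_index = a$interval_index,
    m = vapply(mn, `[[`, numeric(1), "m"),
    n = vapply(mn, `[[`, numeric(1), "n"),
    x_sat = a$x_sat,
    y_fluct = a$y_fluct,
    delta_sf = a$delta_sf,
    norm_sid = a$norm_sid,
    hw_disch = a$hw_disch,
    stringsAsFactors = FALSE
  )
}

#' Detect an abrupt per-vital change in a window
#'
#' TRUE iff any per-vital window mean lies strictly above the mapped clinical
#' maximum or strictly below the mapped clinical minimum. Without history the
#' mapped limits are the population clinical limits; with a history of the
#' person's running mean saturation (X) and fluctuation (Y) values, the band
#' is widened by `max(0, (mean_y - mean_x)) / in_cint_max` noise-floor units
#' (a fluctuation-heavy history tolerates transients; a saturation-heavy one
#' does not). Boundary ties resolve to "no change".
#'
#' @param window An `interval_window`.
#' @param calib A [calibration_spec()].
#' @param history Optional list with `mean_x` and `mean_y`, running means of
#'   the person's X and Y values.
#' @return Logical scalar.
#' @export
detect_abrupt_change <- function(window, calib, history = NULL) {
  widen <- 0
  if (!is.null(history)) {
    widen <- max(0, (history$mean_y - history$mean_x)) / calib$in_cint_max
  }
  for (v in names(calib$clinical_limits)) {
    lim <- calib$clinical_limits[[v]]
    slack <- widen * calib$noise_floor[[v]]
    mv <- mean(window$readings[[v]])
    if (mv > lim[2] + slack || mv < lim[1] - slack) return(TRUE)
  }
  FALSE
}

#' Train the saturation/fluctuation random forest
#'
#' Probability forest (default 200 trees, class-balanced case weights, fixed
#' seed, single thread) on the interval feature table. Labels come from the
#' simulator's ground-truth event log: intervals overlapping an artifact
#' event are `fluctuation`, intervals overlapping a sustained drift are
#' `saturation`. Out-of-bag accuracy is reported in the model metadata.
#'
#' @param features Feature data frame (must contain the columns of
#'   [build_features()]).
#' @param labels Character or factor vector, one of `"saturation"`,
#'   `"fluctuation"` per row.
#' @param hyper Named list of overrides: `num_trees`, `max_depth`,
#'   `mtry`.
#' @param seed Integer seed for the forest.
#' @return Object of class `forest_model`.
#' @export
train_forest <- function(features, labels, hyper = list(), seed = 1L) {
  labels <- factor(as.character(labels),
                   levels = c("saturation", "fluctuation"))
  if (any(is.na(labels))) stop("labels must be saturation/fluctuation")
  if (nlevels(droplevels(labels)) < 2) {
    stop("training set must contain both classes")
  }
  num_trees <- hyper$num_trees %||% 200
  max_depth <- hyper$max_depth %||% 0   # 0 = unlimited in ranger
  X <- features[, .feature_cols, drop = FALSE]
  stopifnot(all(vapply(X, function(c) all(is.finite(c)), logical(1))))
  dat <- cbind(X, .label = labels)
  tab <- table(labels)
  w <- as.numeric(1 / tab[labels]) * length(labels) / 2
  fit <- ranger::ranger(
    dependent.variable.name = ".label",
    data = dat,
    probability = TRUE,
    num.trees = num_trees,
    max.depth = max_depth,
    mtry = hyper$mtry %||% NULL,
    case.weights = w,
    seed = seed,
    num.threads = 1
  )
  structure(list(
    fit = fit,
    meta = list(n_trees = num_trees, max_depth = max_depth, seed = seed,
                class_balance = as.list(tab),
                oob_error = fit$prediction.error)
  ), class = "forest_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify intervals with a trained forest
#'
#' Returns the fluctuation-class probability as the classifier output score
#' (in `[0, 1]`), the arg-max label, and a provisional `"normal"` status; the
#' correlation stage owns the final normal/abnormal decision (fluctuation
#' labels enter the consistency re-check there).
#'
#' @param model A `forest_model`.
#' @param fv Feature data frame (one or more rows).
#' @return Data frame `exists_o`, `label`, `status`.
#' @export
classify_interval <- function(model, fv) {
  stopifnot(inherits(model, "forest_model"))
  X <- fv[, .feature_cols, drop = FALSE]
  if (!all(vapply(X, function(c) all(is.finite(c)), logical(1)))) {
    stop("feature vector with non-finite entries")
  }
  pr <- stats::predict(model$fit, data = X, num.threads = 1)$predictions
  p_fluct <- pr[, "fluctuation"]
  data.frame(
    exists_o = as.numeric(p_fluct),
    label = ifelse(p_fluct > 0.5, "fluctuation", "saturation"),
    status = "normal",
    stringsAsFactors = FALSE
  )
}

#' Label intervals from the ground-truth event log
#'
#' An interval is `fluctuation` if its step span overlaps an artifact event,
#' `saturation` if it overlaps a sustained drift event (drift wins when both
#' overlap, since the drift dominates the window), and `NA` otherwise
#' (no-event intervals are not forest training material).
#'
#' @param assessment Assessment table with `person_id`, `step_start`,
#'   `step_end`.
#' @param events Ground-truth event log.
#' @return Character vector, one of `"saturation"`, `"fluctuation"`, `NA`.
#' @export
label_intervals <- function(assessment, events) {
  out <- rep(NA_character_, nrow(assessment))
  if (!nrow(events)) return(out)
  for (i in seq_len(nrow(assessment))) {
    ev <- events[events$person_id == assessment$person_id[i] &
                   events$kind != "dropout" &
                   events$start <= assessment$step_end[i] &
                   events$end >= assessment$step_start[i], , drop = FALSE]
    if (nrow(ev)) {
      out[i] <- if (any(ev$kind == "saturation")) "saturation" else "fluctuation"
    }
  }
  out
}
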