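#' @title Sensing-interval statistics
#' @description Windows a person's vitals stream into fixed-length sensing
#'   intervals and computes the per-interval assessment statistics: the net
#'   evidence score SId (in-range minus out-of-range reading counts), the
#'   fluctuation magnitude Delta_sf against the personal healthy baseline
#'   PSId, the discharge indicator, the saturation count X (pinned
#'   out-of-range readings), the fluctuation value Y, the normalized score
#'   Norm(SId), and the interval-series consistency statistic.
#' @name sensing_core
NULL

# Guard-activation log: epsilon guards are never silent; each activation is
# counted here by site name.
.cv_guards <- new.env(parent = emptyenv())

log_guard <- function(site) {
  cur <- get0(site, envir = .cv_guards, ifnotfound = 0L)
  assign(site, cur + 1L, envir = .cv_guards)
  invisible(NULL)
}

#' Epsilon-guard activation counts
#'
#' Divisions in the interval statistics are protected by a configurable
#' epsilon; every activation is counted by call site so silent saturation of
#' a guard can be audited.
#'
#' @param reset If `TRUE`, zero the counters after reading them.
#' @return Named integer vector of activation counts per guard site.
#' @export
guard_log <- function(reset = FALSE) {
  sites <- ls(.cv_guards)
  counts <- vapply(sites, function(s) get(s, envir = .cv_guards), integer(1))
  if (reset) rm(list = sites, envir = .cv_guards)
  counts
}

#' Initialize a personal healthy baseline (PSId)
#'
#' The baseline holds per-vital running means of healthy (normal-status)
#' intervals. Before any normal interval has been observed it is seeded with
#' clinical mid-range values.
#'
#' @param person_id Person identifier.
#' @param psid Named numeric vector of per-vital means (`spo2`, `pulse`,
#'   `temp`).
#' @return An object of class `person_baseline`.
#' @export
person_baseline <- function(person_id,
                            psid = c(spo2 = 98, pulse = 80, temp = 36.8)) {
  stopifnot(all(c("spo2", "pulse", "temp") %in% names(psid)))
  structure(list(person_id = person_id,
                 psid = psid[c("spo2", "pulse", "temp")],
                 n_updates = 0L),
            class = "person_baseline")
}

# logical vector: reading i has every vital inside its clinical band
readings_in_range <- function(readings, calib) {
  ok <- rep(TRUE, nrow(readings))
  for (v in names(calib$clinical_limits)) {
    lim <- calib$clinical_limits[[v]]
    ok <- ok & readings[[v]] >= lim[1] & readings[[v]] <= lim[2]
  }
  ok
}

#' Construct an interval window from raw readings
#'
#' @param readings Data frame with at least `spo2`, `pulse`, `temp` (and
#'   `step`, filled in 0-based if absent).
#' @param person_id Person identifier.
#' @param interval_index 1-based interval index.
#' @return An `interval_window` object.
#' @export
interval_window <- function(readings, person_id = "P0001",
                            interval_index = 1L) {
  stopifnot(all(c("spo2", "pulse", "temp") %in% names(readings)))
  if (is.null(readings$step)) readings$step <- seq_len(nrow(readings)) - 1L
  structure(list(person_id = person_id,
                 interval_index = as.integer(interval_index),
                 readings = readings),
            class = "interval_window")
}

#' Window a stream into sensing intervals
#'
#' Consecutive non-overlapping windows of `interval_length` readings (by
#' position in the step-sorted stream, so dropped readings simply shorten
#' windows' step spans). A trailing partial window shorter than half the
#' interval length is discarded, otherwise kept.
#'
#' @param stream One person's stream data frame, sorted by step.
#' @param calib A [calibration_spec()].
#' @return List of `interval_window` objects (fields `person_id`,
#'   `interval_index` starting at 1, `readings`).
#' @export
window_stream <- function(stream, calib) {
  if (nrow(stream) == 0) stop("empty stream")
  stopifnot(!is.unsorted(stream$step))
  L <- calib$interval_length
  n <- nrow(stream)
  n_full <- n %/% L
  rem <- n %% L
  bounds <- if (n_full > 0) {
    lapply(seq_len(n_full), function(i) ((i - 1) * L + 1):(i * L))
  } else list()
  if (rem > 0 && rem >= L / 2) {
    bounds[[length(bounds) + 1]] <- (n_full * L + 1):n
  }
  if (!length(bounds)) stop("stream too short for a single window")
  lapply(seq_along(bounds), function(i) {
    structure(list(person_id = stream$person_id[1],
                   interval_index = i,
                   readings = stream[bounds[[i]], , drop = FALSE]),
              class = "interval_window")
  })
}

#' Net evidence score SId of one interval
#'
#' Count of readings with every vital inside the clinical limits minus the
#' count of readings with any vital outside: positive SId is non-infected
#' evidence, negative SId infected evidence, on the reading-count scale.
#'
#' @param window An `interval_window`.
#' @param calib A [calibration_spec()].
#' @return Integer score in `[-n_readings, n_readings]`.
#' @export
compute_sid <- function(window, calib) {
  r <- window$readings
  if (nrow(r) == 0) stop("empty window")
  ok <- readings_in_range(r, calib)
  sum(ok) - sum(!ok)
}

#' Baseline score: SId evaluated on the personal healthy means
#'
#' The baseline means stand in for a virtual interval of `interval_length`
#' identical readings; while they stay inside the clinical band the score is
#' `+interval_length`.
#'
#' @param baseline A [person_baseline()].
#' @param calib A [calibration_spec()].
#' @return Integer score.
#' @export
psid_score <- function(baseline, calib) {
  m <- baseline$psid
  ok <- all(vapply(names(calib$clinical_limits), function(v) {
    lim <- calib$clinical_limits[[v]]
    m[[v]] >= lim[1] && m[[v]] <= lim[2]
  }, logical(1)))
  if (ok) calib$interval_length else -calib$interval_length
}

#' Sensing-fluctuation magnitude Delta_sf
#'
#' `Delta_sf = (1/(2*pi)) * pop_ratio^2 * (SId - PSId_score)^2`, where
#' `pop_ratio` is the interval's infected-evidence (out-of-range) count over
#' its non-infected-evidence (in-range) count, epsilon-guarded.
#'
#' @param window An `interval_window`.
#' @param baseline A [person_baseline()].
#' @param calib A [calibration_spec()].
#' @param pop_ratio Optional override of the evidence-count ratio.
#' @return Non-negative scalar.
#' @export
compute_delta_sf <- function(window, baseline, calib, pop_ratio = NULL) {
  sid <- compute_sid(window, calib)
  ps <- psid_score(baseline, calib)
  if (is.null(pop_ratio)) {
    ok <- readings_in_range(window$readings, calib)
    n_in <- sum(ok); n_out <- sum(!ok)
    if (n_in == 0) log_guard("delta_sf_pop_ratio")
    pop_ratio <- n_out / (n_in + calib$epsilon)
  }
  (1 / (2 * pi)) * pop_ratio^2 * (sid - ps)^2
}

#' Hardware-discharge indicator of an interval index
#'
#' `HwDisch = (interval_index - cint_min) / in_cint_max`, clipped below at 0:
#' discharge pressure grows linearly once the series passes the minimum
#' consistent-interval bound.
#'
#' @param interval_index 1-based interval index.
#' @param calib A [calibration_spec()].
#' @return Non-negative scalar.
#' @export
compute_hw_disch <- function(interval_index, calib) {
  if (calib$in_cint_max == 0) stop("in_cint_max must be non-zero")
  max(0, (interval_index - calib$cint_min) / calib$in_cint_max)
}

#' Saturation count X of one interval
#'
#' Number of readings that are out of clinical range AND pinned: every
#' vital's absolute first difference from the previous reading is strictly
#' below its noise floor. The first reading has no predecessor and never
#' counts; a one-reading window returns 0 by convention. Spiky out-of-range
#' readings (large first differences) are fluctuations, not saturation, and
#' do not count.
#'
#' @param window An `interval_window`.
#' @param calib A [calibration_spec()].
#' @return Integer in `[0, n_readings - 1]`.
#' @export
compute_x_saturation <- function(window, calib) {
  r <- window$readings
  n <- nrow(r)
  if (n < 2) return(0L)
  out <- !readings_in_range(r, calib)
  pinned <- rep(TRUE, n - 1)
  for (v in names(calib$noise_floor)) {
    pinned <- pinned & abs(diff(r[[v]])) < calib$noise_floor[[v]]
  }
  sum(out[-1] & pinned)
}

#' Fluctuation value Y over a set of intervals
#'
#' `Y = | (1/device_count) * (1/max(Delta_sf - 1, eps)) *
#'   sum_i (SId_i - PSId_score) * (cint_min - in_cint_max)^2 |`,
#' with `Delta_sf` taken from the most recent supplied window unless
#' overridden. Returned as an absolute magnitude.
#'
#' @param windows List of `interval_window` objects (often length 1: the
#'   current interval).
#' @param baseline A [person_baseline()].
#' @param calib A [calibration_spec()].
#' @param device_count Number of wearable devices contributing (default 1,
#'   one device per person).
#' @param delta_sf Optional Delta_sf override.
#' @return Non-negative scalar.
#' @export
compute_y_fluctuation <- function(windows, baseline, calib,
                                  device_count = 1, delta_sf = NULL) {
  stopifnot(length(windows) >= 1)
  if (is.null(delta_sf)) {
    delta_sf <- compute_delta_sf(windows[[length(windows)]], baseline, calib)
  }
  denom <- delta_sf - 1
  if (denom <= calib$epsilon) log_guard("y_delta_sf_denom")
  denom <- max(denom, calib$epsilon)
  ps <- psid_score(baseline, calib)
  s <- sum(vapply(windows, function(w) compute_sid(w, calib) - ps, numeric(1)))
  abs((1 / device_count) * (1 / denom) * s *
        (calib$cint_min - calib$in_cint_max)^2)
}

#' Normalized interval score Norm(SId)
#'
#' `Norm(SId) = X^2 * (cint_min / in_cint_max) - Y^2`: saturation raises the
#' normalized score, fluctuation lowers it.
#'
#' @param x_sat Saturation count X.
#' @param y_fluct Fluctuation value Y.
#' @param calib A [calibration_spec()].
#' @return Scalar.
#' @export
normalize_sid <- function(x_sat, y_fluct, calib) {
  if (calib$in_cint_max == 0) stop("in_cint_max must be non-zero")
  x_sat^2 * (calib$cint_min / calib$in_cint_max) - y_fluct^2
}

#' Interval-series consistency statistic
#'
#' Root-sum-of-squares of the per-interval ratios `Norm(SId)_i / SId_i`
#' chained with the baseline-correlation term
#' `(1 - PSId_score / (SId_last * max(X_last, eps)))^2`. Zero divisions are
#' epsilon-guarded and logged.
#'
#' @param windows List of `interval_window` objects.
#' @param baseline A [person_baseline()].
#' @param calib A [calibration_spec()].
#' @return Non-negative scalar.
#' @export
consistency_sequence <- function(windows, baseline, calib) {
  if (!length(windows)) stop("empty window list")
  ps <- psid_score(baseline, calib)
  stats_i <- lapply(windows, function(w) {
    sid <- compute_sid(w, calib)
    x <- compute_x_saturation(w, calib)
    y <- compute_y_fluctuation(list(w), baseline, calib)
    list(sid = sid, x = x, norm = normalize_sid(x, y, calib))
  })
  ratios <- vapply(stats_i, function(s) {
    sid <- s$sid
    if (sid == 0) { log_guard("consistency_sid_zero"); sid <- calib$epsilon }
    (s$norm / sid)^2
  }, numeric(1))
  last <- stats_i[[length(stats_i)]]
  sid_last <- last$sid
  if (sid_last == 0) { log_guard("consistency_sid_zero"); sid_last <- calib$epsilon }
  x_last <- last$x
  if (x_last < calib$epsilon) log_guard("consistency_x_zero")
  term_last <- (1 - ps / (sid_last * max(x_last, calib$epsilon)))^2
  sqrt(sum(ratios) + term_last)
}

#' Update the personal healthy baseline from a normal interval
#'
#' Per-vital running mean updated with the window means; abnormal windows are
#' rejected so PSId stays a convex combination of healthy window means only.
#'
#' @param baseline A [person_baseline()].
#' @param window An `interval_window`.
#' @param status Status the correlation stage assigned to the window,
#'   `"normal"` or `"abnormal"`.
#' @return The updated `person_baseline`.
#' @export
update_baseline <- function(baseline, window, status = "normal") {
  if (!identical(status, "normal")) {
    stop("update_baseline: abnormal windows never modify PSId")
  }
  m <- c(spo2 = mean(window$readings$spo2),
         pulse = mean(window$readings$pulse),
         temp = mean(window$readings$temp))
  k <- baseline$n_updates
  baseline$psid <- (baseline$psid * k + m) / (k + 1)
  baseline$n_updates <- k + 1L
  baseline
}

#' Assess all intervals of one person's stream
#'
#' Runs the full per-interval statistic set and returns the interval table
#' (export schema
#' `person_id,interval_index,sid,delta_sf,hw_disch,x_sat,y_fluct,norm_sid`
#' plus in/out reading counts and the step span used for ground-truth event
#' matching).
#'
#' @param stream One person's stream data frame.
#' @param baseline A [person_baseline()].
#' @param calib A [calibration_spec()].
#' @return Data frame, one row per kept interval.
#' @export
assess_stream <- function(stream, baseline, calib) {
  windows <- window_stream(stream, calib)
  ps <- psid_score(baseline, calib)
  rows <- lapply(windows, function(w) {
    ok <- readings_in_range(w$readings, calib)
    sid <- sum(ok) - sum(!ok)
    dsf <- compute_delta_sf(w, baseline, calib)
    x <- compute_x_saturation(w, calib)
    y <- compute_y_fluctuation(list(w), baseline, calib, delta_sf = dsf)
    data.frame(
      person_id = w$person_id,
      interval_index = w$interval_index,
      sid = sid,
      delta_sf = dsf,
      hw_disch = compute_hw_disch(w$interval_index, calib),
      x_sat = x,
      y_fluct = y,
      norm_sid = normalize_sid(x, y, calib),
      n_in = sum(ok),
      n_out = sum(!ok),
      step_start = min(w$readings$step),
      step_end = max(w$readings$step),
      n_readings = nrow(w$readings),
      psid_score = ps,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
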