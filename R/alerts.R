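#' @title Discharge estimation, violation detection and recommendations
#' @description Device-discharge probability over the active device set,
#'   threshold-distance violation detection (spatial grid with an exact
#'   brute-force contract), coded safety recommendations, false-rate
#'   mitigation and the iterative consistency-check procedure.
#' @name alerts_and_discharge
NULL

#' Hardware-discharge probability over the active device set
#'
#' Per device s the raw value follows the discharge formula:
#' `raw_s = cr_s * n_dev * |cint_min - in_cint_max|^(i-1) /
#'   sum_t cr_t * n_dev * (1 - sigmaO_t)^(i-1)`,
#' where `cr` is the device's abnormal/normal reading-count ratio and the
#' base of the numerator power is taken in absolute value so the result
#' cannot alternate sign with the interval index. The raw values are then
#' normalized to a probability distribution over devices
#' (`sum rho_hwdc = 1` exactly). The operating flag `omega` is 0 when the
#' device's probability exceeds `cutoff` or its battery is below 5 %,
#' else 1.
#'
#' @param device_stats Data frame with one row per active device:
#'   `device_id`, `count_ratio` (abnormal/normal reading counts), `sigma_o`
#'   (the wearer's current correlation output), `battery` (fraction).
#' @param calib A [calibration_spec()].
#' @param i Interval index (>= 1).
#' @param cutoff Discharge probability cutoff for `omega` (default 0.5).
#' @return Data frame `device_id`, `rho_raw`, `rho_hwdc`, `omega`.
#' @export
hw_discharge_probability <- function(device_stats, calib, i, cutoff = 0.5) {
  stopifnot(i >= 1)
  if (nrow(device_stats) == 0) stop("empty device set")
  n_dev <- nrow(device_stats)
  cr <- device_stats$count_ratio
  denom <- sum(cr * n_dev * (1 - device_stats$sigma_o)^(i - 1))
  if (denom == 0) stop("all-zero denominator in discharge probability")
  raw <- cr * n_dev * abs(calib$cint_min - calib$in_cint_max)^(i - 1) / denom
  total <- sum(raw)
  if (total == 0) stop("all-zero discharge weights")
  rho <- raw / total
  data.frame(
    device_id = device_stats$device_id,
    rho_raw = raw,
    rho_hwdc = rho,
    omega = ifelse(rho > cutoff | device_stats$battery < 0.05, 0L, 1L),
    stringsAsFactors = FALSE
  )
}

# O(n^2) reference scan; the grid-accelerated path must match it exactly.
violations_brute <- function(positions, abnormal, threshold) {
  n <- nrow(positions)
  out <- list()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (!(abnormal[a] || abnormal[b])) next
      d <- sqrt((positions$x[a] - positions$x[b])^2 +
                  (positions$y[a] - positions$y[b])^2)
      if (d < threshold) {
        out[[length(out) + 1]] <- data.frame(
          person_id = positions$person_id[a],
          counterpart_id = positions$person_id[b],
          distance = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(person_id = character(), counterpart_id = character(),
               distance = numeric(), stringsAsFactors = FALSE)
}

#' Detect threshold-distance violations at one time step
#'
#' One alert per unordered pair closer than `threshold` in which at least
#' one member is currently assessed abnormal. The default implementation
#' bins positions into a uniform grid of `threshold`-sized cells and only
#' compares 3x3 cell neighbourhoods; its output is identical to the
#' brute-force all-pairs scan (`method = "brute"`).
#'
#' @param positions Data frame `person_id`, `x`, `y` at the current step.
#' @param abnormal Logical vector aligned with `positions`: the person's
#'   current health assessment.
#' @param threshold Threshold distance in metres (> 0).
#' @param method `"grid"` (default) or `"brute"`.
#' @return Data frame `person_id`, `counterpart_id`, `distance`, each
#'   unordered pair stored once (row order: first person's row index, then
#'   second's).
#' @export
detect_violations <- function(positions, abnormal, threshold,
                              method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(threshold > 0, nrow(positions) == length(abnormal))
  if (nrow(positions) < 2) {
    return(data.frame(person_id = character(), counterpart_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  if (method == "brute") {
    return(violations_brute(positions, abnormal, threshold))
  }
  cx <- floor(positions$x / threshold)
  cy <- floor(positions$y / threshold)
  cell <- paste(cx, cy)
  members <- split(seq_len(nrow(positions)), cell)
  pairs_a <- integer(0); pairs_b <- integer(0)
  seen <- new.env(parent = emptyenv())
  for (key in names(members)) {
    idx <- members[[key]]
    c0 <- as.numeric(strsplit(key, " ", fixed = TRUE)[[1]])
    for (dx in -1:1) for (dy in -1:1) {
      nkey <- paste(c0[1] + dx, c0[2] + dy)
      jdx <- members[[nkey]]
      if (is.null(jdx)) next
      for (a in idx) for (b in jdx) {
        if (a >= b) next
        if (!(abnormal[a] || abnormal[b])) next
        pk <- paste(a, b)
        if (!is.null(seen[[pk]])) next
        seen[[pk]] <- TRUE
        d <- sqrt((positions$x[a] - positions$x[b])^2 +
                    (positions$y[a] - positions$y[b])^2)
        if (d < threshold) {
          pairs_a <- c(pairs_a, a); pairs_b <- c(pairs_b, b)
        }
      }
    }
  }
  if (!length(pairs_a)) {
    return(data.frame(person_id = character(), counterpart_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  ord <- order(pairs_a, pairs_b)
  pairs_a <- pairs_a[ord]; pairs_b <- pairs_b[ord]
  data.frame(
    person_id = positions$person_id[pairs_a],
    counterpart_id = positions$person_id[pairs_b],
    distance = sqrt((positions$x[pairs_a] - positions$x[pairs_b])^2 +
                      (positions$y[pairs_a] - positions$y[pairs_b])^2),
    stringsAsFactors = FALSE
  )
}

#' Issue coded safety recommendations and alerts
#'
#' For every person-interval assessed abnormal: a `device_discharge` alert
#' if the wearer's device is flagged non-operating (`omega = 0`, no health
#' recommendation is issued for a dead device); otherwise an
#' `abnormal_health` alert whose recommendation code follows the branch of
#' the interval inputs — `isolate` when saturation dominates fluctuation
#' (`X > Y`, the `N = 0` path: treat as infected, isolate) and
#' `psid_with_sid` otherwise (the `M + N = SId` path on an operating device:
#' review the current score against the personal healthy baseline). Each
#' distance violation additionally raises a `distance_violation` alert with
#' code `maintain_distance`.
#'
#' @param statuses Data frame `person_id`, `interval_index`, `status`,
#'   `x_sat`, `y_fluct`.
#' @param violations Data frame from [detect_violations()], with an
#'   `interval_index` column appended by the caller.
#' @param discharge Data frame from [hw_discharge_probability()] plus a
#'   `person_id` column.
#' @return Alert data frame `kind`, `person_id`, `counterpart_id`,
#'   `interval_index`, `distance`, `recommendation_text`.
#' @export
issue_recommendations <- function(statuses, violations, discharge) {
  alerts <- list()
  omega <- stats::setNames(discharge$omega, discharge$person_id)
  abn <- statuses[statuses$status == "abnormal", , drop = FALSE]
  for (i in seq_len(nrow(abn))) {
    pid <- abn$person_id[i]
    if (!is.na(omega[pid]) && omega[pid] == 0) {
      alerts[[length(alerts) + 1]] <- data.frame(
        kind = "device_discharge", person_id = pid,
        counterpart_id = NA_character_,
        interval_index = abn$interval_index[i], distance = NA_real_,
        recommendation_text = "replace_device", stringsAsFactors = FALSE)
    } else {
      code <- if (abn$x_sat[i] > abn$y_fluct[i]) "isolate" else "psid_with_sid"
      alerts[[length(alerts) + 1]] <- data.frame(
        kind = "abnormal_health", person_id = pid,
        counterpart_id = NA_character_,
        interval_index = abn$interval_index[i], distance = NA_real_,
        recommendation_text = code, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(violations) && nrow(violations)) {
    for (i in seq_len(nrow(violations))) {
      alerts[[length(alerts) + 1]] <- data.frame(
        kind = "distance_violation", person_id = violations$person_id[i],
        counterpart_id = violations$counterpart_id[i],
        interval_index = violations$interval_index[i],
        distance = violations$distance[i],
        recommendation_text = "maintain_distance", stringsAsFactors = FALSE)
    }
  }
  if (length(alerts)) do.call(rbind, alerts) else
    data.frame(kind = character(), person_id = character(),
               counterpart_id = character(), interval_index = integer(),
               distance = numeric(), recommendation_text = character(),
               stringsAsFactors = FALSE)
}

#' False-rate mitigation over a correlated series
#'
#' Where the gate `sigma_O > Y/X` is open, the corrected score
#' `SId + sigma_O * existsO_i` (the M-property) replaces the raw series
#' output; because the corrected score lives on the SId scale, the
#' interval's branch tag is rewritten to the lower branch so the
#' persistence decision applies SId polarity. Where the gate is closed the
#' series is untouched — mitigation can never flip a closed-gate interval.
#'
#' @param series Output of [correlate_series()].
#' @param sid Numeric vector of interval SId values (aligned).
#' @return The series with `exists_oi`/`branch` corrected and a logical
#'   `mitigated` column.
#' @export
false_rate_mitigation <- function(series, sid) {
  stopifnot(nrow(series) == length(sid))
  gate <- series$sigma_o > series$y_over_x
  out <- series
  out$mitigated <- gate
  out$exists_oi[gate] <- sid[gate] + series$sigma_o[gate] * series$exists_oi[gate]
  out$branch[gate] <- "below"
  out
}

#' Iterative consistency-check procedure
#'
#' Starting from a person's classification history counts, repeatedly
#' evaluate `sigma_O` from the smoothed status probabilities; while
#' `sigma_O > Y/X`, perform the mu fluctuation function for consistency and
#' record the re-checked interval as consistent (raising `rho_cint`, hence
#' strictly lowering `sigma_O`); otherwise reset to the first-interval
#' inputs `M = SId`, `N = 0` and recompute the fluctuation magnitude. The
#' loop ends when `sigma_O <= Y/X` or at the iteration cap.
#'
#' @param n_consistent,n_inconsistent Counts of saturation- and
#'   fluctuation-labelled intervals in the person's history.
#' @param y_over_x Current fluctuation/saturation ratio `Y/X`.
#' @param mu_args Named list with `m`, `n`, `sid`, `exists_o` used in the mu
#'   evaluations.
#' @param cap Iteration cap (default 100).
#' @return List `iterations`, `converged`, `sigma_o_final`, `diverged`.
#' @export
consistency_check_procedure <- function(n_consistent, n_inconsistent,
                                        y_over_x, mu_args, cap = 100) {
  it <- 0L
  nc <- n_consistent; ni <- n_inconsistent
  repeat {
    n <- nc + ni
    rho_c <- (nc + 1) / (n + 2)
    rho_i <- (ni + 1) / (n + 2)
    so <- compute_sigma_o(rho_c, rho_i)
    if (so <= y_over_x) {
      return(list(iterations = it, converged = TRUE,
                  sigma_o_final = so, diverged = FALSE))
    }
    if (it >= cap) {
      return(list(iterations = it, converged = FALSE,
                  sigma_o_final = so, diverged = TRUE))
    }
    mu_function(mu_args$m, mu_args$n, mu_args$sid, mu_args$exists_o, so)
    nc <- nc + 1L
    it <- it + 1L
  }
}
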