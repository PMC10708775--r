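#' Simulation configuration
#'
#' Bundles every knob of the synthetic crowd generator: population size and
#' infected fraction, arena geometry, time base, sensing-interval length, the
#' rates of injected signal events (transient artifacts, sustained drifts,
#' dropouts), battery decay, the proximity alert threshold and the master
#' seed. Identical configurations (including the seed) produce byte-identical
#' streams and event logs.
#'
#' @param n_people Number of people in the crowd (>= 1).
#' @param infected_fraction Proportion of infected people in `[0, 1]`;
#'   exactly `round(n_people * infected_fraction)` people are infected.
#' @param arena_size Numeric length-2 vector, arena width and height in metres.
#' @param n_steps Number of time steps (sensor readings per person).
#' @param dt Seconds between consecutive readings.
#' @param interval_length Readings per sensing interval (window length).
#' @param artifact_rate Expected transient artifacts per person per 100
#'   readings.
#' @param saturation_rate Expected sustained out-of-range drift events per
#'   person per run.
#' @param dropout_prob Per-reading probability that a reading is lost.
#' @param battery_decay Battery fraction lost per reading (linear decay from 1).
#' @param threshold_distance Minimum allowed separation in metres between an
#'   abnormal-status person and others; closer pairs raise alerts. Default 2 m,
#'   the common public-health distancing convention.
#' @param infected_shift Named numeric vector of baseline shifts applied to
#'   infected people's vitals means: `spo2` (percentage points), `pulse` (bpm),
#'   `temp` (deg C).
#' @param artifact_amplitude Peak deviation of an injected transient artifact,
#'   expressed as a multiple of each vital's out-of-range excursion unit.
#' @param noise_sd Named numeric vector of per-reading Gaussian noise standard
#'   deviations for `spo2`, `pulse`, `temp`.
#' @param seed Integer master seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(n_people = 10, infected_fraction = 0.2, seed = 7)
#' cfg$n_people
simulation_config <- function(n_people = 200,
                              infected_fraction = 0.2,
                              arena_size = c(50, 50),
                              n_steps = 200,
                              dt = 1,
                              interval_length = 10,
                              artifact_rate = 2,
                              saturation_rate = 1,
                              dropout_prob = 0.01,
                              battery_decay = 5e-4,
                              threshold_distance = 2,
                              infected_shift = c(spo2 = -6, pulse = 20, temp = 1.5),
                              artifact_amplitude = 1,
                              noise_sd = c(spo2 = 0.3, pulse = 1.5, temp = 0.05),
                              seed = 1L) {
  stopifnot(
    "n_people must be a positive count" = is.numeric(n_people) && n_people >= 1,
    "infected_fraction must be in [0, 1]" =
      is.numeric(infected_fraction) && infected_fraction >= 0 && infected_fraction <= 1,
    "arena_size must be two positive lengths" =
      length(arena_size) == 2 && all(arena_size > 0),
    "n_steps must be a positive count" = n_steps >= 1,
    "dt must be positive" = dt > 0,
    "interval_length must be a positive count" = interval_length >= 1,
    "artifact_rate must be non-negative" = artifact_rate >= 0,
    "saturation_rate must be non-negative" = saturation_rate >= 0,
    "dropout_prob must be a probability" = dropout_prob >= 0 && dropout_prob <= 1,
    "battery_decay must be non-negative" = battery_decay >= 0,
    "threshold_distance must be positive" = threshold_distance > 0,
    "seed must be a single integer" = is.numeric(seed) && length(seed) == 1
  )
  vital_names <- c("spo2", "pulse", "temp")
  stopifnot(all(vital_names %in% names(infected_shift)),
            all(vital_names %in% names(noise_sd)))
  structure(list(
    n_people = as.integer(n_people),
    infected_fraction = infected_fraction,
    arena_size = as.numeric(arena_size),
    n_steps = as.integer(n_steps),
    dt = dt,
    interval_length = as.integer(interval_length),
    artifact_rate = artifact_rate,
    saturation_rate = saturation_rate,
    dropout_prob = dropout_prob,
    battery_decay = battery_decay,
    threshold_distance = threshold_distance,
    infected_shift = infected_shift[vital_names],
    artifact_amplitude = artifact_amplitude,
    noise_sd = noise_sd[vital_names],
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Calibration of the sensing-interval assessment
#'
#' Holds the interval-consistency bounds `cint_min` (minimum consistent
#' fluctuation bound) and `in_cint_max` (maximum inconsistent fluctuation
#' bound) that parameterise the discharge indicator, the normalization, and
#' the fluctuation magnitude; the per-vital clinical limits separating normal
#' from abnormal readings; per-vital pinning floors below which consecutive
#' first differences count as a flat (saturated) signal; and the epsilon guard
#' used in every division.
#'
#' Clinical limits default to the conventional adult resting ranges:
#' SpO2 >= 94 %, pulse 60-100 bpm, temperature < 38.0 deg C (lower bound
#' 35.0 deg C for hypothermia).
#'
#' @param cint_min Minimum consistent-fluctuation bound (count, >= 0).
#' @param in_cint_max Maximum inconsistent-fluctuation bound (count, > 0).
#' @param interval_length Readings per sensing interval.
#' @param clinical_limits Named list of `c(low, high)` per vital.
#' @param noise_floor Named numeric vector of per-vital pinning floors
#'   (same units as the vital): a first difference strictly below the floor is
#'   treated as "no movement" when counting saturated readings.
#' @param epsilon Small positive guard for divisions (default 1e-9).
#'
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(cint_min = 2,
                             in_cint_max = 5,
                             interval_length = 10,
                             clinical_limits = list(
                               spo2 = c(94, 100),
                               pulse = c(60, 100),
                               temp = c(35.0, 38.0)
                             ),
                             noise_floor = c(spo2 = 0.5, pulse = 2, temp = 0.1),
                             epsilon = 1e-9) {
  stopifnot(
    "in_cint_max must be > 0" = in_cint_max > 0,
    "cint_min must be >= 0" = cint_min >= 0,
    "interval_length must be >= 1" = interval_length >= 1,
    "epsilon must be > 0" = epsilon > 0
  )
  vital_names <- c("spo2", "pulse", "temp")
  stopifnot(all(vital_names %in% names(clinical_limits)),
            all(vital_names %in% names(noise_floor)))
  structure(list(
    cint_min = cint_min,
    in_cint_max = in_cint_max,
    interval_length = as.integer(interval_length),
    clinical_limits = clinical_limits[vital_names],
    noise_floor = noise_floor[vital_names],
    epsilon = epsilon
  ), class = "calibration_spec")
}

# Deterministic child seed below 2^31, derived from the master seed and a salt
# so that independently callable generator stages stay reproducible.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(salt) * 16807) %% 2147483647)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_people, "people,",
      sprintf("%.0f%% infected,", 100 * x$infected_fraction),
      x$n_steps, "steps, interval", x$interval_length,
      ", seed", x$seed, "\n")
  invisible(x)
}

#' @export
print.calibration_spec <- function(x, ...) {
  cat("<calibration_spec> cint_min =", x$cint_min,
      ", in_cint_max =", x$in_cint_max,
      ", interval_length =", x$interval_length, "\n")
  invisible(x)
}
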