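#' @title Synthetic crowd generation
#' @description Seeded generators for a crowd of people wearing vitals
#'   sensors: ground-truth infection status, personal healthy baselines,
#'   random-waypoint movement in a rectangular arena, per-reading vitals with
#'   injected transient artifacts (fluctuations) and sustained out-of-range
#'   drifts (saturations), battery decay and reading dropouts. Every injected
#'   event is recorded in a ground-truth event log so downstream stages can be
#'   scored against it.
#' @name synthetic_crowd
NULL

# Healthy adult sampling ranges for baseline means; infected baselines are
# these plus config$infected_shift.
.healthy_ranges <- list(
  spo2 = c(97, 99),
  pulse = c(60, 100),
  temp = c(36.5, 37.2)
)

# Out-of-range excursion unit per vital: the deviation added by one injected
# event at amplitude 1 (sign chosen to leave the clinical band).
.excursion_unit <- c(spo2 = -8, pulse = 30, temp = 2)

#' Generate a population with ground-truth infection status
#'
#' Draws `n_people` persons with unique device ids, healthy baseline vitals
#' sampled uniformly from conventional adult resting ranges (SpO2 97-99 %,
#' pulse 60-100 bpm, temperature 36.5-37.2 deg C) and uniform start positions
#' in the arena. Exactly `round(n_people * infected_fraction)` persons are
#' flagged infected by a seeded draw without replacement; their baseline means
#' are shifted by `config$infected_shift` (default SpO2 -6 points, pulse
#' +20 bpm, temperature +1.5 deg C).
#'
#' @param config A [simulation_config()].
#' @return A data frame with one row per person: `person_id`, `device_id`,
#'   `person_idx`, `infected`, baseline means `spo2_mean`, `pulse_mean`,
#'   `temp_mean`, and start position `x0`, `y0`.
#' @export
#' @examples
#' pop <- generate_population(simulation_config(n_people = 10, seed = 7))
#' sum(pop$infected)
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_people
  set.seed(derive_seed(config$seed, 11L))
  n_inf <- round(n * config$infected_fraction)
  infected <- rep(FALSE, n)
  if (n_inf > 0) infected[sample.int(n, n_inf)] <- TRUE

  base <- vapply(names(.healthy_ranges), function(v) {
    r <- .healthy_ranges[[v]]
    stats::runif(n, r[1], r[2])
  }, numeric(n))
  base <- matrix(base, nrow = n,
                 dimnames = list(NULL, names(.healthy_ranges)))
  shift <- config$infected_shift
  for (v in colnames(base)) {
    base[infected, v] <- base[infected, v] + shift[[v]]
  }
  data.frame(
    person_id = sprintf("P%04d", seq_len(n)),
    device_id = sprintf("D%04d", seq_len(n)),
    person_idx = seq_len(n),
    infected = infected,
    spo2_mean = base[, "spo2"],
    pulse_mean = base[, "pulse"],
    temp_mean = base[, "temp"],
    x0 = stats::runif(n, 0, config$arena_size[1]),
    y0 = stats::runif(n, 0, config$arena_size[2]),
    stringsAsFactors = FALSE
  )
}

#' Simulate 2-D crowd movement (random waypoint)
#'
#' Each person walks toward a uniformly drawn waypoint at a personal speed
#' (0.5-1.5 m/s), picking a fresh waypoint on arrival. Positions are clipped
#' to the arena. Step 0 is the start position; one row per person per step.
#'
#' @param population Output of [generate_population()].
#' @param config A [simulation_config()].
#' @return Data frame `person_id`, `step` (0-based), `x`, `y`.
#' @export
simulate_movement <- function(population, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(population) == 0) stop("empty population")
  w <- config$arena_size[1]; h <- config$arena_size[2]
  n_steps <- config$n_steps
  out <- vector("list", nrow(population))
  for (p in seq_len(nrow(population))) {
    set.seed(derive_seed(config$seed, 100L + population$person_idx[p]))
    speed <- stats::runif(1, 0.5, 1.5) * config$dt
    x <- numeric(n_steps); y <- numeric(n_steps)
    x[1] <- min(max(population$x0[p], 0), w)
    y[1] <- min(max(population$y0[p], 0), h)
    wx <- stats::runif(1, 0, w); wy <- stats::runif(1, 0, h)
    if (n_steps > 1) {
      for (s in 2:n_steps) {
        dx <- wx - x[s - 1]; dy <- wy - y[s - 1]
        d <- sqrt(dx^2 + dy^2)
        if (d < speed) {
          x[s] <- wx; y[s] <- wy
          wx <- stats::runif(1, 0, w); wy <- stats::runif(1, 0, h)
        } else {
          x[s] <- x[s - 1] + speed * dx / d
          y[s] <- y[s - 1] + speed * dy / d
        }
        x[s] <- min(max(x[s], 0), w)
        y[s] <- min(max(y[s], 0), h)
      }
    }
    out[[p]] <- data.frame(person_id = population$person_id[p],
                           step = seq_len(n_steps) - 1L,
                           x = x, y = y, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate one person's vitals stream with injected events
#'
#' Per-reading vitals are the person's baseline means plus Gaussian noise.
#' Transient artifacts (1-3 readings, sign-alternating spikes of amplitude
#' `artifact_amplitude` excursion units) and sustained drifts (out-of-range
#' excursions lasting at least one full sensing interval) are injected at the
#' configured rates; every injected event is returned in the ground-truth
#' event log.
#'
#' @param person One row of [generate_population()] output.
#' @param config A [simulation_config()].
#' @param positions Optional data frame of this person's positions
#'   (`step`, `x`, `y`); defaults to the start position held constant.
#' @return A list with `stream` (data frame `person_id,device_id,step,spo2,
#'   pulse,temp,battery,x,y`) and `events` (data frame
#'   `person_id,kind,start,end`, steps inclusive).
#' @export
generate_vitals_stream <- function(person, config, positions = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_steps
  set.seed(derive_seed(config$seed, 1000L + person$person_idx))
  base <- c(spo2 = person$spo2_mean, pulse = person$pulse_mean,
            temp = person$temp_mean)
  sds <- config$noise_sd
  vit <- sapply(c("spo2", "pulse", "temp"), function(v) {
    rep(base[[v]], n) + if (sds[[v]] > 0) stats::rnorm(n, 0, sds[[v]]) else 0
  })
  vit <- matrix(vit, nrow = n, dimnames = list(NULL, c("spo2", "pulse", "temp")))

  events <- list()
  # transient artifacts: spiky, sign-alternating within the event
  n_art <- stats::rpois(1, config$artifact_rate * n / 100)
  if (n_art > 0 && config$artifact_amplitude != 0) {
    for (k in seq_len(n_art)) {
      len <- sample(1:3, 1)
      start <- sample.int(max(n - len + 1, 1), 1)
      idx <- start:(start + len - 1)
      signs <- (-1)^(seq_along(idx) - 1)
      for (v in colnames(vit)) {
        vit[idx, v] <- vit[idx, v] +
          signs * config$artifact_amplitude * .excursion_unit[[v]]
      }
      events[[length(events) + 1]] <-
        data.frame(person_id = person$person_id, kind = "artifact",
                   start = start - 1L, end = start + len - 2L,
                   stringsAsFactors = FALSE)
    }
  }
  # sustained drifts: pinned out-of-range for >= one full interval
  n_sat <- stats::rpois(1, config$saturation_rate)
  if (n_sat > 0) {
    for (k in seq_len(n_sat)) {
      len <- sample(config$interval_length:(2 * config$interval_length), 1)
      len <- min(len, n)
      start <- sample.int(max(n - len + 1, 1), 1)
      idx <- start:(start + len - 1)
      for (v in colnames(vit)) {
        vit[idx, v] <- base[[v]] + .excursion_unit[[v]]
      }
      events[[length(events) + 1]] <-
        data.frame(person_id = person$person_id, kind = "saturation",
                   start = start - 1L, end = start + len - 2L,
                   stringsAsFactors = FALSE)
    }
  }
  if (is.null(positions)) {
    pos <- data.frame(step = seq_len(n) - 1L, x = person$x0, y = person$y0)
  } else {
    pos <- positions[order(positions$step), c("step", "x", "y")]
    stopifnot(nrow(pos) == n)
  }
  stream <- data.frame(
    person_id = person$person_id,
    device_id = person$device_id,
    step = seq_len(n) - 1L,
    spo2 = vit[, "spo2"],
    pulse = vit[, "pulse"],
    temp = vit[, "temp"],
    battery = 1.0,
    x = pos$x, y = pos$y,
    stringsAsFactors = FALSE
  )
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(person_id = character(), kind = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  list(stream = stream, events = ev)
}

#' Apply battery decay and reading dropouts to a stream
#'
#' Battery decays linearly by `battery_decay` per reading starting from 1.0
#' (floored at 0); each reading is independently dropped with probability
#' `dropout_prob`. Dropped readings are removed from the stream (absent rows,
#' not NaN rows) and recorded in the event log with kind `"dropout"`.
#'
#' @param stream_obj A list as returned by [generate_vitals_stream()].
#' @param config A [simulation_config()].
#' @return A list with the thinned `stream` and the augmented `events` log.
#' @export
inject_hardware_discharge <- function(stream_obj, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$battery_decay < 0) stop("battery_decay must be >= 0")
  stream <- stream_obj$stream
  if (nrow(stream) == 0) stop("stream must be non-empty")
  k <- seq_len(nrow(stream))
  stream$battery <- pmax(1 - config$battery_decay * k, 0)
  salt <- 5000L + sum(utf8ToInt(stream$person_id[1]))
  set.seed(derive_seed(config$seed, salt))
  drop <- stats::runif(nrow(stream)) < config$dropout_prob
  events <- stream_obj$events
  if (any(drop)) {
    dropped <- stream$step[drop]
    events <- rbind(events, data.frame(
      person_id = stream$person_id[1], kind = "dropout",
      start = dropped, end = dropped, stringsAsFactors = FALSE))
  }
  list(stream = stream[!drop, , drop = FALSE], events = events)
}

#' Simulate a full crowd: population, movement, vitals, hardware
#'
#' Convenience wrapper running [generate_population()],
#' [simulate_movement()], [generate_vitals_stream()] and
#' [inject_hardware_discharge()] for every person under one seed.
#'
#' @param config A [simulation_config()].
#' @return A list with `population`, `movement`, `stream` (all persons,
#'   row-bound) and `events` (ground-truth event log).
#' @export
simulate_crowd <- function(config) {
  pop <- generate_population(config)
  mov <- simulate_movement(pop, config)
  streams <- vector("list", nrow(pop))
  events <- vector("list", nrow(pop))
  for (p in seq_len(nrow(pop))) {
    pos <- mov[mov$person_id == pop$person_id[p], ]
    so <- generate_vitals_stream(pop[p, ], config, positions = pos)
    so <- inject_hardware_discharge(so, config)
    streams[[p]] <- so$stream
    events[[p]] <- so$events
  }
  list(population = pop,
       movement = mov,
       stream = do.call(rbind, c(streams, list(make.row.names = FALSE))),
       events = do.call(rbind, c(events, list(make.row.names = FALSE))))
}
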