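# Fixtures built in code: windows from raw vitals, random windows for the
# oracle-equivalence suites, tiny crowd configurations.

vitals_window <- function(spo2, pulse = rep(80, length(spo2)),
                          temp = rep(36.8, length(spo2)),
                          person_id = "P0001", interval_index = 1L) {
  interval_window(
    data.frame(person_id = person_id, device_id = "D0001",
               step = seq_along(spo2) - 1L,
               spo2 = spo2, pulse = pulse, temp = temp,
               battery = 1, x = 0, y = 0, stringsAsFactors = FALSE),
    person_id = person_id, interval_index = interval_index)
}

# random window mixing in-range and out-of-range readings
random_window <- function(n = 10, interval_index = 1L) {
  spo2 <- ifelse(stats::runif(n) < 0.5,
                 stats::runif(n, 95, 99), stats::runif(n, 82, 92))
  vitals_window(spo2,
                pulse = stats::runif(n, 60, 100),
                temp = stats::runif(n, 36, 37.5),
                interval_index = interval_index)
}

default_calib <- function(...) calibration_spec(...)

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_people = 20, infected_fraction = 0.25, n_steps = 60,
                   interval_length = 10, seed = 5L)
  do.call(simulation_config, utils::modifyList(defaults, args))
}
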