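test_that("population counts, infected draw and baseline separation", {
  pop <- generate_population(simulation_config(n_people = 10,
                                               infected_fraction = 0.2,
                                               seed = 7))
  expect_equal(nrow(pop), 10)
  expect_equal(sum(pop$infected), 2)
  expect_equal(anyDuplicated(pop$device_id), 0)

  pop0 <- generate_population(simulation_config(n_people = 4,
                                                infected_fraction = 0))
  expect_equal(sum(pop0$infected), 0)

  big <- generate_population(simulation_config(n_people = 1000,
                                               infected_fraction = 0.1,
                                               seed = 1))
  expect_lt(mean(big$spo2_mean[big$infected]),
            mean(big$spo2_mean[!big$infected]))
})

test_that("config validation rejects bad inputs", {
  expect_error(simulation_config(n_people = 0), "n_people")
  expect_error(simulation_config(infected_fraction = 1.2), "infected_fraction")
  expect_error(simulation_config(threshold_distance = 0), "threshold_distance")
})

test_that("movement stays in the arena and starts at the start position", {
  cfg <- simulation_config(n_people = 5, arena_size = c(10, 10),
                           n_steps = 50, seed = 9)
  pop <- generate_population(cfg)
  mov <- simulate_movement(pop, cfg)
  expect_equal(nrow(mov), 5 * 50)
  expect_true(all(mov$x >= 0 & mov$x <= 10))
  expect_true(all(mov$y >= 0 & mov$y <= 10))
  first <- mov[mov$step == 0, ]
  expect_equal(first$x[order(first$person_id)],
               pop$x0[order(pop$person_id)])

  cfg1 <- simulation_config(n_people = 1, n_steps = 1, seed = 2)
  pop1 <- generate_population(cfg1)
  expect_equal(nrow(simulate_movement(pop1, cfg1)), 1)
  expect_error(simulate_movement(pop1[0, ], cfg1), "empty")
})

test_that("noise-free event-free stream is constant at baseline", {
  cfg <- simulation_config(n_people = 1, infected_fraction = 0, n_steps = 30,
                           artifact_rate = 0, saturation_rate = 0,
                           noise_sd = c(spo2 = 0, pulse = 0, temp = 0),
                           seed = 4)
  pop <- generate_population(cfg)
  so <- generate_vitals_stream(pop[1, ], cfg)
  expect_equal(unique(so$stream$spo2), pop$spo2_mean[1])
  expect_equal(unique(so$stream$pulse), pop$pulse_mean[1])
  expect_equal(nrow(so$events), 0)
})

test_that("streams are deterministic under a fixed seed", {
  cfg <- tiny_config()
  pop <- generate_population(cfg)
  a <- generate_vitals_stream(pop[3, ], cfg)
  b <- generate_vitals_stream(pop[3, ], cfg)
  expect_identical(a, b)
})

test_that("event accounting: every logged artifact is realized in the stream", {
  cfg <- simulation_config(n_people = 1, infected_fraction = 0, n_steps = 200,
                           artifact_rate = 5, saturation_rate = 2,
                           noise_sd = c(spo2 = 0, pulse = 0, temp = 0),
                           seed = 11)
  pop <- generate_population(cfg)
  so <- generate_vitals_stream(pop[1, ], cfg)
  art <- so$events[so$events$kind == "artifact", ]
  base <- pop$spo2_mean[1]
  for (i in seq_len(nrow(art))) {
    span <- so$stream$spo2[(art$start[i] + 1):(art$end[i] + 1)]
    expect_true(any(abs(span - base) > 1),
                info = sprintf("artifact %d leaves no trace", i))
  }
  sat <- so$events[so$events$kind == "saturation", ]
  expect_true(all(sat$end - sat$start + 1 >= cfg$interval_length))
})

test_that("hardware discharge: battery arithmetic and dropout rate", {
  cfg0 <- simulation_config(n_people = 1, n_steps = 30, dropout_prob = 0,
                            battery_decay = 0, seed = 1)
  pop <- generate_population(cfg0)
  so <- generate_vitals_stream(pop[1, ], cfg0)
  out <- inject_hardware_discharge(so, cfg0)
  expect_identical(out$stream$spo2, so$stream$spo2)
  expect_true(all(out$stream$battery == 1))

  cfg2 <- simulation_config(n_people = 1, n_steps = 500, dropout_prob = 0,
                            battery_decay = 0.001, seed = 1)
  pop2 <- generate_population(cfg2)
  out2 <- inject_hardware_discharge(generate_vitals_stream(pop2[1, ], cfg2),
                                    cfg2)
  expect_equal(out2$stream$battery[500], 0.5)

  cfg3 <- simulation_config(n_people = 1, n_steps = 10000,
                            dropout_prob = 0.1, seed = 3)
  pop3 <- generate_population(cfg3)
  out3 <- inject_hardware_discharge(generate_vitals_stream(pop3[1, ], cfg3),
                                    cfg3)
  frac <- 1 - nrow(out3$stream) / 10000
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(frac - 0.1), 3 * se)
  expect_equal(sum(out3$events$kind == "dropout"), 10000 - nrow(out3$stream))
})

test_that("stream files round-trip losslessly", {
  cfg <- tiny_config(n_people = 3)
  sim <- simulate_crowd(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stream(sim$stream, path)
  back <- read_stream(path)
  rownames(back) <- NULL
  orig <- sim$stream[order(sim$stream$person_id, sim$stream$step), ]
  rownames(orig) <- NULL
  expect_equal(back, orig, tolerance = 1e-12)

  ev_path <- withr::local_tempfile(fileext = ".jsonl")
  write_event_log(sim$events, ev_path)
  ev <- read_event_log(ev_path)
  expect_equal(nrow(ev), nrow(sim$events))

  empty <- sim$stream[0, ]
  write_stream(empty, path)
  expect_equal(length(readLines(path)), 1)  # header only
})
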