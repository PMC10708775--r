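calib <- default_calib()
base <- person_baseline("P0001")

test_that("windowing keeps full windows and applies the half-length rule", {
  mk_stream <- function(n) data.frame(
    person_id = "P0001", device_id = "D0001", step = seq_len(n) - 1L,
    spo2 = 98, pulse = 80, temp = 36.8, battery = 1, x = 0, y = 0)
  cal5 <- calibration_spec(interval_length = 5)
  expect_length(window_stream(mk_stream(10), cal5), 2)   # 2 full
  expect_length(window_stream(mk_stream(12), cal5), 2)   # trailing 2 < 2.5 dropped
  expect_length(window_stream(mk_stream(4), cal5), 1)    # partial 4 >= 2.5 kept
  expect_length(window_stream(mk_stream(17), cal5), 3)   # trailing 2 dropped
  expect_error(window_stream(mk_stream(5)[0, ], cal5), "empty")
})

test_that("SId counts in-range minus out-of-range readings", {
  expect_equal(compute_sid(vitals_window(rep(98, 5)), calib), 5)
  expect_equal(compute_sid(vitals_window(rep(85, 5)), calib), -5)
  expect_equal(compute_sid(vitals_window(c(98, 97, 96, 85, 85)), calib), 1)
  # any single vital out of band flips the reading
  expect_equal(compute_sid(vitals_window(rep(98, 3),
                                         temp = c(36.8, 38.5, 36.8)), calib), 1)
  w_empty <- vitals_window(98)
  w_empty$readings <- w_empty$readings[0, , drop = FALSE]
  expect_error(compute_sid(w_empty, calib), "empty")
})

test_that("delta_sf zero at baseline and invertible at sqrt(2*pi)", {
  w <- vitals_window(rep(98, 10))
  expect_equal(compute_delta_sf(w, base, calib), 0)
  # pop_ratio 1 and deviation sqrt(2*pi) give exactly 1
  w2 <- vitals_window(rep(85, 10))
  ps <- psid_score(base, calib)
  dev <- sqrt(2 * pi)
  d <- compute_delta_sf(w2, base, calib, pop_ratio = 1)
  expect_equal(d, (1 / (2 * pi)) * (compute_sid(w2, calib) - ps)^2)
  expect_equal((1 / (2 * pi)) * 1^2 * dev^2, 1)
})

test_that("discharge indicator is linear above cint_min and clipped at 0", {
  cal <- calibration_spec(cint_min = 5, in_cint_max = 10)
  expect_equal(compute_hw_disch(5, cal), 0)
  expect_equal(compute_hw_disch(15, cal), 1.0)
  expect_equal(compute_hw_disch(3, cal), 0)
})

test_that("X counts pinned out-of-range readings only", {
  expect_equal(compute_x_saturation(vitals_window(rep(98, 5)), calib), 0)
  expect_equal(compute_x_saturation(vitals_window(rep(85, 5)), calib), 4)
  spiky <- vitals_window(c(85, 92, 84, 93, 85))  # large first differences
  expect_equal(compute_x_saturation(spiky, calib), 0)
  expect_equal(compute_x_saturation(vitals_window(85), calib), 0)
})

test_that("Y is zero at baseline and linear in the SId deviations", {
  w <- vitals_window(rep(98, 10))
  expect_equal(compute_y_fluctuation(list(w), base, calib), 0)
  w1 <- vitals_window(c(rep(98, 8), 85, 85))
  w2 <- vitals_window(c(rep(98, 6), 85, 85, 85, 85))
  ps <- psid_score(base, calib)
  d1 <- compute_sid(w1, calib) - ps   # -4
  d2 <- compute_sid(w2, calib) - ps   # -8 = 2 * d1
  dsf <- 5  # fixed so the denominator guard stays inactive
  y1 <- compute_y_fluctuation(list(w1), base, calib, delta_sf = dsf)
  y2 <- compute_y_fluctuation(list(w2), base, calib, delta_sf = dsf)
  expect_equal(d2, 2 * d1)
  expect_equal(y2, 2 * y1)
})

test_that("normalization combines saturation and fluctuation quadratically", {
  cal_eq <- calibration_spec(cint_min = 3, in_cint_max = 3)
  expect_equal(normalize_sid(1, 0, cal_eq), 1)
  cal_h <- calibration_spec(cint_min = 1, in_cint_max = 2)
  expect_equal(normalize_sid(2, 1, cal_h), 1.0)  # 4 * 0.5 - 1
  expect_equal(normalize_sid(0, 0, calib), 0)
})

test_that("consistency statistic vanishes when every term is zero", {
  # Norm = 0 (X = 0, Y = 0), SId = PSId_score and X chosen so the last term
  # needs the full-range window with the closing term evaluated directly
  w <- vitals_window(rep(98, 10))
  got <- consistency_sequence(list(w), base, calib)
  # Norm = 0 so only the closing term survives: (1 - 10/(10 * eps))^2
  ps <- psid_score(base, calib)
  expect_equal(got, abs(1 - ps / (10 * max(0, calib$epsilon))))
  # adding a window with Norm(SId) = 0 and the same closing term changes nothing
  got2 <- consistency_sequence(list(w, w), base, calib)
  expect_equal(got2, got)
  expect_error(consistency_sequence(list(), base, calib), "empty")
})

test_that("baseline updates only from normal windows and stays convex", {
  b <- person_baseline("P0001")
  w1 <- vitals_window(rep(97, 10), pulse = rep(70, 10), temp = rep(36.6, 10))
  b1 <- update_baseline(b, w1, "normal")
  expect_equal(unname(b1$psid["spo2"]), 97)
  b2 <- update_baseline(b1, w1, "normal")
  expect_equal(b2$psid, b1$psid)
  expect_error(update_baseline(b2, w1, "abnormal"), "abnormal")
  # convex combination: running mean of window means stays inside their hull
  set.seed(1)
  b3 <- person_baseline("P0001")
  means <- numeric(20)
  for (i in 1:20) {
    v <- runif(1, 95, 99)
    means[i] <- v
    b3 <- update_baseline(b3, vitals_window(rep(v, 10)), "normal")
  }
  expect_gte(b3$psid[["spo2"]], min(means))
  expect_lte(b3$psid[["spo2"]], max(means))
})

test_that("assessment statistics are pure: recomputation reproduces the table", {
  cfg <- tiny_config(n_people = 2)
  sim <- simulate_crowd(cfg)
  sp <- sim$stream[sim$stream$person_id == sim$population$person_id[1], ]
  a1 <- assess_stream(sp, base, calib)
  a2 <- assess_stream(sp, base, calib)
  expect_identical(a1, a2)
  # stored fields match the individual operations
  win <- window_stream(sp, calib)
  for (i in seq_along(win)) {
    expect_identical(a1$sid[i], compute_sid(win[[i]], calib))
    expect_identical(a1$x_sat[i], compute_x_saturation(win[[i]], calib))
    expect_equal(a1$hw_disch[i], compute_hw_disch(i, calib))
  }
})
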