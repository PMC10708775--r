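calib <- default_calib()

test_that("discharge probabilities normalize and flag dead devices", {
  one <- data.frame(device_id = "D1", count_ratio = 0.4, sigma_o = 0,
                    battery = 0.9, stringsAsFactors = FALSE)
  d1 <- hw_discharge_probability(one, calib, i = 3)
  expect_equal(d1$rho_hwdc, 1.0)
  expect_equal(d1$omega, 0L)  # a lone device carries all the probability

  two <- data.frame(device_id = c("D1", "D2"), count_ratio = c(0.3, 0.3),
                    sigma_o = c(0.2, 0.2), battery = c(0.9, 0.9),
                    stringsAsFactors = FALSE)
  d2 <- hw_discharge_probability(two, calib, i = 5)
  expect_equal(d2$rho_hwdc, c(0.5, 0.5))
  expect_equal(sum(d2$rho_hwdc), 1, tolerance = 1e-12)
  expect_equal(d2$omega, c(1L, 1L))

  # low battery forces omega = 0 regardless of probability
  two$battery[2] <- 0.01
  expect_equal(hw_discharge_probability(two, calib, i = 5)$omega, c(1L, 0L))

  expect_error(hw_discharge_probability(one[0, ], calib, 1), "empty")
  zero <- data.frame(device_id = "D1", count_ratio = 0, sigma_o = 0,
                     battery = 1, stringsAsFactors = FALSE)
  expect_error(hw_discharge_probability(zero, calib, 2), "denominator")
})

test_that("discharge matches the direct formula oracle", {
  set.seed(15)
  for (r in 1:100) {
    nd <- sample(2:6, 1)
    dv <- data.frame(device_id = paste0("D", seq_len(nd)),
                     count_ratio = runif(nd, 0.05, 2),
                     sigma_o = runif(nd, -2, 0.9),
                     battery = runif(nd), stringsAsFactors = FALSE)
    i <- sample(1:6, 1)
    got <- hw_discharge_probability(dv, calib, i)
    want <- or_discharge(dv$count_ratio, dv$sigma_o,
                         calib$cint_min, calib$in_cint_max, i)
    expect_equal(got$rho_hwdc, want, tolerance = 1e-9)
    expect_equal(sum(got$rho_hwdc), 1, tolerance = 1e-12)
  }
})

test_that("violation detection follows the abnormal-member rule", {
  pos <- data.frame(person_id = c("A", "B"), x = c(0, 1), y = c(0, 0),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(detect_violations(pos, c(FALSE, FALSE), 2)), 0)
  v <- detect_violations(pos, c(TRUE, FALSE), 2)
  expect_equal(nrow(v), 1)
  expect_equal(v$distance, 1)
  expect_true(v$distance < 2)
  # symmetry: order of abnormal member does not matter
  v2 <- detect_violations(pos, c(FALSE, TRUE), 2)
  expect_equal(v2$distance, v$distance)
  expect_equal(nrow(detect_violations(pos[1, , drop = FALSE], TRUE, 2)), 0)
})

test_that("grid detection equals the brute-force scan on random crowds", {
  set.seed(5)
  for (r in 1:10) {
    n <- sample(50:150, 1)
    pos <- data.frame(person_id = sprintf("P%03d", 1:n),
                      x = runif(n, 0, 30), y = runif(n, 0, 30),
                      stringsAsFactors = FALSE)
    abn <- runif(n) < 0.3
    g <- detect_violations(pos, abn, 2, method = "grid")
    b <- detect_violations(pos, abn, 2, method = "brute")
    expect_equal(g, b)
  }
})

test_that("recommendations gate on status, discharge and violations", {
  st_norm <- data.frame(person_id = "P1", interval_index = 1,
                        status = "normal", x_sat = 0, y_fluct = 0,
                        stringsAsFactors = FALSE)
  disc <- data.frame(device_id = "D1", person_id = "P1", omega = 1L,
                     stringsAsFactors = FALSE)
  expect_equal(nrow(issue_recommendations(st_norm, NULL, disc)), 0)

  st_abn <- st_norm; st_abn$status <- "abnormal"; st_abn$x_sat <- 5
  viol <- data.frame(person_id = "P1", counterpart_id = "P2", distance = 1,
                     interval_index = 1, stringsAsFactors = FALSE)
  al <- issue_recommendations(st_abn, viol, disc)
  expect_gte(nrow(al), 2)
  expect_setequal(al$kind, c("abnormal_health", "distance_violation"))
  expect_equal(al$recommendation_text[al$kind == "abnormal_health"], "isolate")
  # fluctuation-dominated interval gets the baseline-review code
  st_fl <- st_abn; st_fl$x_sat <- 0; st_fl$y_fluct <- 3
  al_fl <- issue_recommendations(st_fl, NULL, disc)
  expect_equal(al_fl$recommendation_text, "psid_with_sid")
  # discharged device: discharge alert, no health recommendation
  disc0 <- disc; disc0$omega <- 0L
  al0 <- issue_recommendations(st_abn, NULL, disc0)
  expect_equal(al0$kind, "device_discharge")
})

test_that("mitigation corrects only open-gate intervals", {
  ser <- data.frame(interval_index = 1:3, branch = c("above", "below", "above"),
                    exists_oi = c(2, -5, 1), sigma_o = c(0.5, -1, 0.4),
                    y_over_x = c(0.1, 3, 0.9), stringsAsFactors = FALSE)
  sid <- c(4, -6, 8)
  out <- false_rate_mitigation(ser, sid)
  expect_equal(out$mitigated, c(TRUE, FALSE, FALSE))
  expect_equal(out$exists_oi[1], 4 + 0.5 * 2)
  expect_equal(out$branch[1], "below")
  expect_equal(out$exists_oi[2:3], ser$exists_oi[2:3])  # gate closed: no-op
  # sigma_o = 0 open-gate case: corrected score equals SId
  ser0 <- data.frame(interval_index = 1, branch = "above", exists_oi = 3,
                     sigma_o = 0, y_over_x = -1, stringsAsFactors = FALSE)
  expect_equal(false_rate_mitigation(ser0, 7)$exists_oi, 7)
})

test_that("consistency-check procedure terminates and caps", {
  mu_args <- list(m = 1, n = 0.2, sid = 5, exists_o = 0.4)
  # already below: zero iterations
  r0 <- consistency_check_procedure(4, 4, y_over_x = 0.5, mu_args)
  expect_equal(r0$iterations, 0)
  expect_true(r0$converged)
  # inconsistent-heavy history must iterate down to the ratio
  r1 <- consistency_check_procedure(0, 10, y_over_x = 0.2, mu_args)
  expect_true(r1$converged)
  expect_gt(r1$iterations, 0)
  expect_lte(r1$sigma_o_final, 0.2)
  # tiny cap forces the divergence flag
  r2 <- consistency_check_procedure(0, 500, y_over_x = 0, mu_args, cap = 3)
  expect_false(r2$converged)
  expect_true(r2$diverged)
})
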