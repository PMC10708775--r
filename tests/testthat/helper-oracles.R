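# Independent direct-evaluation oracles: straight-line transliterations of
# the interval statistics, written against raw numeric inputs and never
# calling the package's own implementations.

or_limits <- list(spo2 = c(94, 100), pulse = c(60, 100), temp = c(35, 38))
or_floors <- c(spo2 = 0.5, pulse = 2, temp = 0.1)

or_reading_ok <- function(row, limits = or_limits) {
  row[["spo2"]] >= limits$spo2[1] && row[["spo2"]] <= limits$spo2[2] &&
    row[["pulse"]] >= limits$pulse[1] && row[["pulse"]] <= limits$pulse[2] &&
    row[["temp"]] >= limits$temp[1] && row[["temp"]] <= limits$temp[2]
}

or_sid <- function(readings, limits = or_limits) {
  s <- 0
  for (i in seq_len(nrow(readings))) {
    s <- s + if (or_reading_ok(readings[i, ], limits)) 1 else -1
  }
  s
}

or_delta_sf <- function(pop_ratio, sid, psid) {
  (1 / (2 * pi)) * pop_ratio^2 * (sid - psid)^2
}

or_x <- function(readings, limits = or_limits, floors = or_floors) {
  cnt <- 0
  for (i in 2:nrow(readings)) {
    pinned <- TRUE
    for (v in c("spo2", "pulse", "temp")) {
      if (abs(readings[[v]][i] - readings[[v]][i - 1]) >= floors[[v]]) {
        pinned <- FALSE
      }
    }
    if (!or_reading_ok(readings[i, ], limits) && pinned) cnt <- cnt + 1
  }
  cnt
}

or_y <- function(sids, psid, delta_sf, cmin, incmax, dev = 1, eps = 1e-9) {
  s <- 0
  for (sid in sids) s <- s + (sid - psid) * (cmin - incmax)^2
  abs((1 / dev) * (1 / max(delta_sf - 1, eps)) * s)
}

or_norm <- function(x, y, cmin, incmax) x^2 * (cmin / incmax) - y^2

or_consistency <- function(norms, sids, psid, x_last, eps = 1e-9) {
  tot <- 0
  for (i in seq_along(norms)) {
    sid <- if (sids[i] == 0) eps else sids[i]
    tot <- tot + (norms[i] / sid)^2
  }
  sid_l <- if (sids[length(sids)] == 0) eps else sids[length(sids)]
  tot <- tot + (1 - psid / (sid_l * max(x_last, eps)))^2
  sqrt(tot)
}

or_mu <- function(m, n, sid, eo, so) {
  list(mu = -m * eo + n * sid + eo * sid * so,
       prop_m = sid + so * eo,
       prop_n = m - so * eo)
}

or_probs <- function(labels) {
  n <- length(labels)
  c(rc = (sum(labels == "saturation") + 1) / (n + 2),
    ri = (sum(labels == "fluctuation") + 1) / (n + 2))
}

# direct iterative evaluation of both branch recursions
or_series <- function(norms, sids, yx, ns, xs, n_in, n_out, labels,
                      eps = 1e-9) {
  k <- length(norms)
  out <- numeric(k)
  branch <- character(k)
  for (i in seq_len(k)) {
    p <- or_probs(labels[seq_len(i)])
    so <- 1 - p[["rc"]] / p[["ri"]]
    if (so > yx[i]) {
      branch[i] <- "above"
      if (i == 1) out[i] <- norms[1] else {
        pm <- or_probs(labels[seq_len(i - 1)])
        out[i] <- norms[i] - yx[i - 1] - pm[["rc"]] / pm[["ri"]]
      }
    } else {
      branch[i] <- "below"
      nsx <- ns[i] * sids[i] * xs[i]
      if (i == 1) out[i] <- sids[1] - nsx else {
        out[i] <- sids[i] - nsx - n_out[i - 1] / max(n_in[i - 1], eps)
      }
    }
  }
  list(exists_oi = out, branch = branch)
}

or_discharge <- function(cr, so, cmin, incmax, i) {
  n_dev <- length(cr)
  den <- 0
  for (t in seq_len(n_dev)) den <- den + cr[t] * n_dev * (1 - so[t])^(i - 1)
  raw <- numeric(n_dev)
  for (s in seq_len(n_dev)) {
    raw[s] <- cr[s] * n_dev * abs(cmin - incmax)^(i - 1) / den
  }
  raw / sum(raw)
}
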