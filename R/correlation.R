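#' @title Post-classification correlation over interval series
#' @description Estimates consistent/inconsistent status probabilities,
#'   computes the correlation output sigma_O, the fluctuation function mu and
#'   its two properties, propagates the branch recursions over a person's
#'   interval series, and makes the persistence-based normal/abnormal
#'   decision.
#' @name correlation_engine
NULL

#' Smoothed consistent/inconsistent status probabilities
#'
#' Add-one (Laplace) smoothed frequencies over the classification history:
#' `rho_cint = (n_saturation + 1) / (n + 2)`,
#' `rho_incint = (n_fluctuation + 1) / (n + 2)`. Saturation-labelled
#' intervals count as consistent status, fluctuation-labelled as
#' inconsistent; smoothing keeps both probabilities strictly positive so the
#' sigma_O ratio never divides by zero.
#'
#' @param labels Character vector of interval labels
#'   (`"saturation"`/`"fluctuation"`).
#' @return Named list `rho_cint`, `rho_incint`.
#' @export
estimate_consistency_probs <- function(labels) {
  n <- length(labels)
  if (n == 0) stop("empty classification history")
  nc <- sum(labels == "saturation")
  ni <- sum(labels == "fluctuation")
  list(rho_cint = (nc + 1) / (n + 2), rho_incint = (ni + 1) / (n + 2))
}

#' Correlation output sigma_O
#'
#' `sigma_O = 1 - rho_cint / rho_incint`. Zero when the two status
#' probabilities are equal; negative when consistent status dominates.
#'
#' @param rho_cint Probability of consistent fluctuation status.
#' @param rho_incint Probability of inconsistent status (> 0).
#' @return Scalar `<= 1`.
#' @export
compute_sigma_o <- function(rho_cint, rho_incint) {
  if (rho_incint <= 0) stop("rho_incint must be > 0")
  1 - rho_cint / rho_incint
}

#' Fluctuation function mu and its two properties
#'
#' `mu = -M * existsO + N * SId + existsO * SId * sigmaO`, with the two
#' properties `prop_m = SId + sigmaO * existsO` and
#' `prop_n = M - sigmaO * existsO`. Each evaluation satisfies whichever
#' property lies closer to mu.
#'
#' @param m,n Classifier inputs M and N.
#' @param sid Interval SId.
#' @param exists_o Classifier output score.
#' @param sigma_o Correlation output.
#' @return Named list `mu`, `prop_m`, `prop_n`, `satisfied`
#'   (`"M"` or `"N"`).
#' @export
mu_function <- function(m, n, sid, exists_o, sigma_o) {
  stopifnot(all(is.finite(c(m, n, sid, exists_o, sigma_o))))
  mu <- -m * exists_o + n * sid + exists_o * sid * sigma_o
  prop_m <- sid + sigma_o * exists_o
  prop_n <- m - sigma_o * exists_o
  satisfied <- if (abs(mu - prop_m) <= abs(mu - prop_n)) "M" else "N"
  list(mu = mu, prop_m = prop_m, prop_n = prop_n, satisfied = satisfied)
}

#' Correlated series outputs over a person's intervals
#'
#' For each interval the running smoothed probabilities give `sigma_O`; the
#' branch condition `sigma_O > Y/X` (ties fall to the lower branch) selects
#' the recursion:
#' \itemize{
#'   \item upper branch: `existsO_1 = Norm(SId)_1`;
#'     `existsO_i = Norm(SId)_i - (Y/X)_{i-1} - (rho_cint/rho_incint)_{i-1}`.
#'   \item lower branch: `existsO_1 = SId_1 - N_1 * SId_1 * X_1`;
#'     `existsO_i = SId_i - N_i * SId_i * X_i - (out/in)_{i-1}` where
#'     `(out/in)` is the previous interval's out-of-range over in-range
#'     reading-count ratio (epsilon-guarded, logged).
#' }
#'
#' @param assessment One person's [assess_stream()] table (ordered).
#' @param features Matching [build_features()] table.
#' @param labels Character vector of interval classification labels.
#' @param calib A [calibration_spec()].
#' @return Data frame `interval_index`, `branch` (`"above"`/`"below"`),
#'   `exists_oi`, `sigma_o`, `rho_cint`, `rho_incint`, `y_over_x`.
#' @export
correlate_series <- function(assessment, features, labels, calib) {
  a <- assessment[order(assessment$interval_index), ]
  f <- features[order(features$interval_index), ]
  n <- nrow(a)
  stopifnot(nrow(f) == n, length(labels) == n)
  eps <- calib$epsilon
  yx <- f$y_fluct / pmax(f$x_sat, eps)
  out_in <- numeric(n)
  for (i in seq_len(n)) {
    if (a$n_in[i] == 0) log_guard("correlate_out_in")
    out_in[i] <- a$n_out[i] / max(a$n_in[i], eps)
  }
  res <- data.frame(interval_index = a$interval_index,
                    branch = character(n), exists_oi = numeric(n),
                    sigma_o = numeric(n), rho_cint = numeric(n),
                    rho_incint = numeric(n), y_over_x = yx,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pr <- estimate_consistency_probs(labels[seq_len(i)])
    so <- compute_sigma_o(pr$rho_cint, pr$rho_incint)
    res$sigma_o[i] <- so
    res$rho_cint[i] <- pr$rho_cint
    res$rho_incint[i] <- pr$rho_incint
    if (so > yx[i]) {
      res$branch[i] <- "above"
      res$exists_oi[i] <- if (i == 1) a$norm_sid[1] else {
        prm <- estimate_consistency_probs(labels[seq_len(i - 1)])
        a$norm_sid[i] - yx[i - 1] - prm$rho_cint / prm$rho_incint
      }
    } else {
      res$branch[i] <- "below"
      nsx <- f$n[i] * a$sid[i] * f$x_sat[i]
      res$exists_oi[i] <- if (i == 1) a$sid[1] - nsx else
        a$sid[i] - nsx - out_in[i - 1]
    }
  }
  res
}

#' Persistence-based normal/abnormal decision
#'
#' Abnormal iff the last `k` series outputs all lie on the abnormal side of
#' the threshold. The abnormal side is branch-aware: outputs of the upper
#' (`sigma_O > Y/X`) recursion scale with Norm(SId), which grows large and
#' positive under sustained saturation, so their abnormal side is
#' `> +threshold`; outputs of the lower recursion scale with SId, which goes
#' negative under out-of-range evidence, so their abnormal side is
#' `< -threshold`. Fewer than `k` outputs, or any of the last `k` on the
#' normal side, give `"normal"` — no single-interval alarms when `k = 2`.
#'
#' @param series Output of [correlate_series()] (or any data frame with
#'   `exists_oi` and `branch`).
#' @param threshold Positive decision threshold (default 1).
#' @param k Persistence length (default 2).
#' @return `"normal"` or `"abnormal"`.
#' @export
decide_status <- function(series, threshold = 1, k = 2) {
  n <- nrow(series)
  if (n == 0) stop("no series outputs")
  if (n < k) return("normal")
  idx <- (n - k + 1):n
  abn <- ifelse(series$branch[idx] == "above",
                series$exists_oi[idx] > threshold,
                series$exists_oi[idx] < -threshold)
  if (all(abn)) "abnormal" else "normal"
}

#' Rolling per-interval statuses
#'
#' Applies [decide_status()] to every prefix of the series, giving the
#' status the system would report after each interval.
#'
#' @inheritParams decide_status
#' @return Character vector of statuses, one per interval.
#' @export
rolling_status <- function(series, threshold = 1, k = 2) {
  vapply(seq_len(nrow(series)), function(i) {
    decide_status(series[seq_len(i), , drop = FALSE], threshold, k)
  }, character(1))
}
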