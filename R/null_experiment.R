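#' Symmetric-null fluctuation-classification experiment
#'
#' Generates interval feature vectors whose saturation and fluctuation
#' classes are exchangeable: the saturation class draws
#' `x_sat ~ N(mu_hi, 1)`, `y_fluct ~ N(mu_lo, 1)` and the fluctuation class
#' the swapped pair, while every other feature is an uninformative standard
#' normal in both classes. Swapping the class labels and the
#' saturation/fluctuation columns leaves the joint distribution invariant,
#' so however well the forest separates the two regimes, the expected
#' fraction of a balanced evaluation set classified as fluctuation is 0.5.
#'
#' @param n Number of feature vectors (split evenly between classes).
#' @param seed Integer seed.
#' @param mu_hi,mu_lo Means of the swap-symmetric Gaussian pair.
#' @return List `features` (data frame in the classifier schema) and
#'   `labels` (character).
#' @export
symmetric_null_features <- function(n, seed, mu_hi = 1, mu_lo = -1) {
  set.seed(seed)
  n_sat <- n %/% 2
  n_fl <- n - n_sat
  lab <- c(rep("saturation", n_sat), rep("fluctuation", n_fl))
  x <- c(stats::rnorm(n_sat, mu_hi), stats::rnorm(n_fl, mu_lo))
  y <- c(stats::rnorm(n_sat, mu_lo), stats::rnorm(n_fl, mu_hi))
  f <- data.frame(
    m = stats::rnorm(n), n = stats::rnorm(n),
    x_sat = x, y_fluct = y,
    delta_sf = stats::rnorm(n), norm_sid = stats::rnorm(n),
    hw_disch = stats::rnorm(n)
  )
  ord <- sample.int(n)
  list(features = f[ord, , drop = FALSE], labels = lab[ord])
}

#' Fluctuation-classified fraction under the symmetric null
#'
#' Trains the random-forest stage on a balanced symmetric-null sample,
#' classifies a fresh balanced set of `n_eval` interval feature vectors, and
#' returns the fraction labelled fluctuation. Under the null this fraction
#' is 0.5 up to binomial noise.
#'
#' @param n_eval Evaluation intervals (default 10000).
#' @param n_train Training intervals (default 2000).
#' @param seed Integer seed controlling both draws and the forest.
#' @return List `fraction`, `n`, `se` (binomial standard error at 0.5).
#' @export
symmetric_null_fluctuation_rate <- function(n_eval = 10000, n_train = 2000,
                                            seed = 1L) {
  tr <- symmetric_null_features(n_train, derive_seed(seed, 31L))
  ev <- symmetric_null_features(n_eval, derive_seed(seed, 32L))
  model <- train_forest(tr$features, tr$labels,
                        seed = derive_seed(seed, 33L))
  res <- classify_interval(model, ev$features)
  list(fraction = mean(res$label == "fluctuation"),
       n = n_eval,
       se = sqrt(0.25 / n_eval))
}
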