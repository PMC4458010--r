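#' Derive a replicate or scenario seed from a master seed
#'
#' Counter-based derivation so that each Monte Carlo replicate (or grid
#' scenario) has its own reproducible seed: identical (master, counter)
#' pairs always map to the same seed, and all derived seeds stay below
#' 2^31 so they are valid R integer seeds.
#'
#' @param master integer master seed.
#' @param counter non-negative integer counter (replicate or scenario index).
#' @return a single integer seed in [1, 2147483629].
#' @export
derive_seed <- function(master, counter) {
  m <- 2147483629
  s0 <- as.numeric(master) %% m
  # multipliers kept small enough that all products are exact doubles
  as.integer((s0 * 48271 + as.numeric(counter) * 16807) %% m + 1)
}

#' ANOVA moment estimator of the intraclass correlation
#'
#' One-way analysis-of-variance moment estimator applied directly to the
#' binary outcomes, using the standard unbalanced-design effective cluster
#' size n0 = (N - sum n_i^2 / N) / (K - 1).
#'
#' @param y binary outcome vector.
#' @param cluster cluster labels, same length as `y`.
#' @return the estimated ICC (can be slightly negative in small samples).
#' @export
icc_anova <- function(y, cluster) {
  cluster <- as.integer(factor(cluster))
  K <- max(cluster)
  if (K < 2L) stop("ICC estimation needs at least two clusters")
  N <- length(y)
  ni <- tabulate(cluster)
  ybar_i <- rowsum(y, cluster)[, 1] / ni
  ybar <- mean(y)
  msb <- sum(ni * (ybar_i - ybar)^2) / (K - 1)
  msw <- sum((y - ybar_i[cluster])^2) / (N - K)
  n0 <- (N - sum(ni^2) / N) / (K - 1)
  (msb - msw) / (msb + (n0 - 1) * msw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
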