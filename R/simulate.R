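# Beta-binomial simulator for two-arm cluster-randomized trials.
#
# Outcomes within a cluster are correlated by drawing the cluster's event
# probability from a Beta(a, b) law whose moments pin the marginal
# proportion mu = a/(a+b) and the intraclass correlation
# rho = 1/(1+a+b), then drawing iid Bernoulli outcomes given that
# probability.  Cluster sizes are normal draws (mean nbar, sd nbar*cv),
# rounded, and clamped below at 1.

#' Beta shape parameters for a given marginal proportion and ICC
#'
#' Inverts the beta-binomial moment identities mu = a/(a+b) and
#' rho = 1/(1+a+b), giving a = mu(1-rho)/rho and b = (1-mu)(1-rho)/rho.
#'
#' @param mu marginal event proportion, in (0, 1).
#' @param rho intraclass correlation, in (0, 1).
#' @return a list with components `a` and `b` (both positive).
#' @examples
#' beta_shapes(0.25, 0.05)   # a = 4.75, b = 14.25
#' @export
beta_shapes <- function(mu, rho) {
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0 || mu >= 1)
    stop("`mu` must be a single proportion strictly inside (0, 1)")
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho >= 1)
    stop("`rho` must be a single ICC strictly inside (0, 1)")
  list(a = mu * (1 - rho) / rho, b = (1 - mu) * (1 - rho) / rho)
}

#' Draw heterogeneous cluster sizes
#'
#' Sizes are drawn from Normal(nbar, (nbar*cv)^2), rounded to the nearest
#' integer, and clamped below at 1 so no cluster is empty.  Uses the
#' current RNG state; seed control belongs to the caller.
#'
#' @param K number of clusters.
#' @param nbar mean cluster size (>= 1).
#' @param cv coefficient of variation of cluster sizes (>= 0); `cv = 0`
#'   gives every cluster exactly `round(nbar)` subjects.
#' @return integer vector of `K` cluster sizes, each >= 1.
#' @export
draw_cluster_sizes <- function(K, nbar, cv) {
  if (K < 1L) stop("`K` must be at least 1")
  if (nbar < 1) stop("`nbar` must be at least 1")
  if (!is.numeric(cv) || cv < 0) stop("`cv` must be non-negative")
  pmax(1L, as.integer(round(rnorm(K, mean = nbar, sd = nbar * cv))))
}

#' Define a simulated CRT scenario
#'
#' Bundles the full generative specification of one simulated two-arm
#' cluster-randomized trial: cluster number and size distribution,
#' within-cluster correlation, control-arm event proportion, intervention
#' odds ratio (applied on the marginal scale) and seed.
#'
#' @param K total number of clusters; must be even and >= 4 (clusters are
#'   split equally across the two arms).
#' @param nbar mean cluster size.
#' @param cv coefficient of variation of cluster sizes.
#' @param icc beta-binomial intraclass correlation, in (0, 1).
#' @param mu_control control-arm marginal event proportion.
#' @param odds_ratio intervention odds ratio on the marginal proportion
#'   (1 under the null).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return an object of class `trial_scenario`.
#' @export
trial_scenario <- function(K, nbar, cv, icc, mu_control = 0.25,
                           odds_ratio = 1, seed = NULL) {
  if (K < 4L || K %% 2L != 0L)
    stop("`K` must be an even integer >= 4 (equal allocation to two arms)")
  if (nbar < 1) stop("`nbar` must be at least 1")
  if (!is.numeric(cv) || cv < 0) stop("`cv` must be non-negative")
  if (icc <= 0 || icc >= 1) stop("`icc` must lie strictly inside (0, 1)")
  if (mu_control <= 0 || mu_control >= 1)
    stop("`mu_control` must lie strictly inside (0, 1)")
  if (odds_ratio <= 0) stop("`odds_ratio` must be positive")
  structure(list(K = as.integer(K), nbar = nbar, cv = cv, icc = icc,
                 mu_control = mu_control, odds_ratio = odds_ratio,
                 seed = seed),
            class = "trial_scenario")
}

#' Construct and validate a CRT dataset
#'
#' @param cluster integer/character cluster labels per subject.
#' @param arm 0/1 treatment arm per subject; must be constant within cluster.
#' @param y 0/1 outcome per subject.
#' @return an object of class `crt_data`: a list with elements `cluster`
#'   (integer labels 1..K), `arm`, `y`, `cluster_sizes`, `cluster_arm`
#'   (arm per cluster), `K` and `N`.
#' @export
crt_data <- function(cluster, arm, y) {
  if (length(cluster) != length(arm) || length(cluster) != length(y))
    stop("`cluster`, `arm` and `y` must have the same length")
  if (!all(y %in% c(0, 1))) {
    bad <- which(!(y %in% c(0, 1)))
    stop("non-binary outcomes at rows: ", paste(head(bad, 5), collapse = ", "))
  }
  if (!all(arm %in% c(0, 1))) stop("`arm` must be coded 0 (control) / 1 (intervention)")
  f <- factor(cluster, levels = unique(cluster))
  idx <- as.integer(f)
  K <- nlevels(f)
  mixed <- tapply(arm, idx, function(a) length(unique(a)) > 1L)
  if (any(mixed))
    stop("arm is not constant within cluster(s): ",
         paste(levels(f)[which(mixed)], collapse = ", "))
  sizes <- tabulate(idx, nbins = K)
  structure(list(cluster = idx, arm = as.integer(arm), y = as.integer(y),
                 cluster_sizes = sizes,
                 cluster_arm = as.integer(tapply(arm, idx, `[`, 1L)),
                 cluster_labels = levels(f),
                 K = K, N = length(y)),
            class = "crt_data")
}

#' @export
as.data.frame.crt_data <- function(x, ...) {
  data.frame(cluster = x$cluster_labels[x$cluster], arm = x$arm, y = x$y,
             stringsAsFactors = FALSE)
}

#' @export
print.crt_data <- function(x, ...) {
  cat("CRT dataset:", x$N, "subjects in", x$K, "clusters",
      sprintf("(%d control / %d intervention)\n",
              sum(x$cluster_arm == 0L), sum(x$cluster_arm == 1L)))
  cat("  cluster sizes:", min(x$cluster_sizes), "-", max(x$cluster_sizes),
      sprintf("(mean %.1f)\n", mean(x$cluster_sizes)))
  cat(sprintf("  crude event rate: %.4f\n", mean(x$y)))
  invisible(x)
}

# odds-ratio shift of a proportion on the marginal scale
apply_odds_ratio <- function(mu, or) {
  odds <- mu / (1 - mu) * or
  odds / (1 + odds)
}

#' Simulate one two-arm CRT under the beta-binomial model
#'
#' The first K/2 clusters form the control arm, the rest the intervention
#' arm (randomizing labels has no distributional effect).  Each cluster
#' draws its event probability from the Beta law matching its arm's
#' marginal proportion and the common ICC; outcomes are iid Bernoulli
#' given that probability.  The intervention-arm marginal proportion is
#' the control proportion with its odds multiplied by `odds_ratio`.
#'
#' @param scenario a [trial_scenario()].
#' @return a [crt_data()] object.  If `scenario$seed` is non-`NULL` the
#'   generator is seeded first, making the dataset a pure function of the
#'   scenario.
#' @export
simulate_trial <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  K <- scenario$K
  sizes <- draw_cluster_sizes(K, scenario$nbar, scenario$cv)
  arm_c <- rep(c(0L, 1L), each = K / 2L)
  mu1 <- apply_odds_ratio(scenario$mu_control, scenario$odds_ratio)
  mus <- ifelse(arm_c == 0L, scenario$mu_control, mu1)
  sh <- lapply(unique(mus), beta_shapes, rho = scenario$icc)
  names(sh) <- as.character(unique(mus))
  p <- vapply(seq_len(K), function(i) {
    s <- sh[[as.character(mus[i])]]
    rbeta(1L, s$a, s$b)
  }, numeric(1))
  y <- unlist(lapply(seq_len(K), function(i) rbinom(sizes[i], 1L, p[i])))
  crt_data(cluster = rep(seq_len(K), times = sizes),
           arm = rep(arm_c, times = sizes), y = y)
}

#' Simulate a CRT directly from the conditional logistic GLMM
#'
#' Generates data from the conditional model: cluster random intercepts
#' b_i ~ N(0, tau2) and logit P(y = 1 | b_i) = alpha + beta * arm + b_i.
#' Used for parameter-recovery experiments where the estimand is defined
#' on the conditional (not marginal) scale.
#'
#' @param K even number of clusters (half per arm).
#' @param nbar mean cluster size.
#' @param cv coefficient of variation of cluster sizes.
#' @param alpha conditional intercept (logit scale).
#' @param beta conditional log odds ratio of the intervention.
#' @param tau2 random-intercept variance.
#' @param seed optional integer seed.
#' @return a [crt_data()] object.
#' @export
simulate_glmm_trial <- function(K, nbar, cv = 0, alpha = qlogis(0.25),
                                beta = log(1.5), tau2 = 0.44, seed = NULL) {
  if (K < 4L || K %% 2L != 0L) stop("`K` must be an even integer >= 4")
  if (tau2 < 0) stop("`tau2` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  sizes <- draw_cluster_sizes(K, nbar, cv)
  arm_c <- rep(c(0L, 1L), each = K / 2L)
  b <- rnorm(K, 0, sqrt(tau2))
  p <- plogis(alpha + beta * arm_c + b)
  y <- unlist(lapply(seq_len(K), function(i) rbinom(sizes[i], 1L, p[i])))
  crt_data(cluster = rep(seq_len(K), times = sizes),
           arm = rep(arm_c, times = sizes), y = y)
}

#' Latent random-intercept variance implied by the beta-binomial generator
#'
#' Fits the random-intercept logistic GLMM to one large single-arm
#' beta-binomial dataset and returns the estimated tau2.  This is a
#' diagnostic of the latent logit-scale variance implied by a given
#' (mu, rho) pair, not a calibrated quantity: the fit carries Monte Carlo
#' and linearization error.
#'
#' @param mu marginal event proportion.
#' @param rho beta-binomial ICC.
#' @param n_clusters number of clusters to simulate (large).
#' @param cluster_size common cluster size (large).
#' @param seed optional integer seed.
#' @return a list with `tau2` (the fitted variance), `phi`, and
#'   `converged`.
#' @export
empirical_random_effect_variance <- function(mu, rho, n_clusters = 2000,
                                             cluster_size = 100,
                                             seed = NULL) {
  sh <- beta_shapes(mu, rho)
  if (!is.null(seed)) set.seed(seed)
  p <- rbeta(n_clusters, sh$a, sh$b)
  y <- unlist(lapply(p, function(pi) rbinom(cluster_size, 1L, pi)))
  cl <- rep(seq_len(n_clusters), each = cluster_size)
  fit <- fit_glmm_core(y = y, cluster = cl,
                       Tmat = matrix(1, nrow = n_clusters, ncol = 1),
                       control = glmm_control())
  list(tau2 = fit$varcomp$tau2, phi = fit$varcomp$phi,
       converged = fit$converged)
}
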