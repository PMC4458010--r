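# Beta-binomial trial generator: moment identities, cluster-size model,
# marginal calibration and determinism.

test_that("beta_shapes inverts the moment identities", {
  s <- beta_shapes(0.25, 0.05)
  expect_equal(s$a, 4.75)
  expect_equal(s$b, 14.25)
  # rho = 1/3 at mu = 1/2 is the uniform distribution
  s2 <- beta_shapes(0.5, 1 / 3)
  expect_equal(s2$a, 1)
  expect_equal(s2$b, 1)
  s3 <- beta_shapes(0.25, 0.001)
  expect_equal(s3$a + s3$b, 999)
  expect_equal(s3$a, 249.75)
  expect_error(beta_shapes(0, 0.05))
  expect_error(beta_shapes(0.25, 1))
  expect_error(beta_shapes(1.2, 0.05))
})

test_that("beta_shapes round-trips mu and rho across random pairs", {
  set.seed(42)
  for (i in 1:1000) {
    mu <- runif(1, 0.01, 0.99); rho <- runif(1, 0.001, 0.9)
    s <- beta_shapes(mu, rho)
    expect_lt(abs(s$a / (s$a + s$b) - mu), 1e-12)
    expect_lt(abs(1 / (1 + s$a + s$b) - rho), 1e-12)
  }
})

test_that("cluster sizes follow the rounded, clamped normal model", {
  set.seed(1)
  expect_identical(draw_cluster_sizes(7, 20, 0), rep(20L, 7))
  # clamping: even at cv = 1 no cluster is empty
  set.seed(2)
  sizes <- replicate(200, min(draw_cluster_sizes(10, 20, 1)))
  expect_true(all(sizes >= 1))
  expect_error(draw_cluster_sizes(10, 20, -0.1))
  # moments at nbar = 50, cv = 0.5 against the exact expectation of the
  # clamped-and-rounded normal draw, computed by quadrature
  set.seed(3)
  x <- draw_cluster_sizes(1e5, 50, 0.5)
  pr <- seq(5e-7, 1 - 5e-7, length.out = 2e5)
  ref <- pmax(1, round(qnorm(pr, 50, 25)))
  expect_lt(abs(mean(x) - mean(ref)), 3 * sd(ref) / sqrt(1e5))
  expect_lt(abs(sd(x) - sd(ref)), 3 * sd(ref) / sqrt(2 * (1e5 - 1)))
})

test_that("simulated trials reproduce the marginal event proportion under the null", {
  mu0 <- 0.25
  sc <- trial_scenario(K = 10, nbar = 20, cv = 0.25, icc = 0.01,
                       mu_control = mu0, odds_ratio = 1)
  tot <- 0; events <- 0; ssq <- 0
  for (r in 1:500) {
    sc$seed <- derive_seed(77, r)
    d <- simulate_trial(sc)
    tot <- tot + d$N; events <- events + sum(d$y)
  }
  # SE of the pooled fraction with the beta-binomial design effect
  deff <- 1 + (20 - 1) * 0.01
  se <- sqrt(mu0 * (1 - mu0) * deff / tot)
  expect_lt(abs(events / tot - mu0), 3 * se)
})

test_that("the intervention arm mean follows the marginal odds ratio", {
  expect_equal(crtddf:::apply_odds_ratio(0.25, 1.5), 1 / 3)
  expect_equal(crtddf:::apply_odds_ratio(0.25, 1), 0.25)
})

test_that("ANOVA ICC estimator recovers the generating rho on large trials", {
  for (rho in c(0.01, 0.05, 0.1)) {
    sc <- trial_scenario(K = 2000, nbar = 50, cv = 0, icc = rho,
                         odds_ratio = 1, seed = round(1e4 * rho) + 5)
    d <- simulate_trial(sc)
    expect_lt(abs(icc_anova(d$y, d$cluster) - rho),
              3 * icc_sd_approx(rho, 50, 2000))
  }
})

test_that("degenerate singleton-cluster trials are iid Bernoulli per arm", {
  sc <- trial_scenario(K = 40, nbar = 1, cv = 0, icc = 0.05, seed = 8)
  d <- simulate_trial(sc)
  expect_true(all(d$cluster_sizes == 1L))
  expect_identical(d$N, d$K)
})

test_that("identical seeds give bit-identical datasets", {
  sc <- trial_scenario(K = 10, nbar = 30, cv = 0.5, icc = 0.05, seed = 99)
  d1 <- simulate_trial(sc)
  d2 <- simulate_trial(sc)
  expect_identical(d1, d2)
  sc$seed <- 100
  expect_false(identical(simulate_trial(sc), d1))
})

test_that("scenario validation rejects impossible configurations", {
  expect_error(trial_scenario(9, 20, 0.5, 0.05), "even")
  expect_error(trial_scenario(10, 20, -1, 0.05))
  expect_error(trial_scenario(10, 20, 0.5, 0))
  expect_error(trial_scenario(10, 20, 0.5, 0.05, mu_control = 1))
  expect_error(trial_scenario(10, 20, 0.5, 0.05, odds_ratio = 0))
})

test_that("latent random-effect variance diagnostic tracks the Beta quadrature value", {
  # near-zero ICC implies a vanishing latent variance; at this problem
  # size the REML sampling noise of tau2-hat is ~2e-3, so 5e-3 is ~3 SD
  e0 <- empirical_random_effect_variance(0.25, 1e-6, 2000, 100, seed = 9)
  expect_lt(e0$tau2, 5e-3)
  # at rho = 0.05 the fitted tau2 should sit near Var(logit p) under the
  # Beta law (PQL linearization attenuates it slightly)
  e1 <- empirical_random_effect_variance(0.25, 0.05, 1500, 100, seed = 9)
  expect_true(e1$converged)
  expect_lt(abs(e1$tau2 - quad_var_logit(0.25, 0.05)) /
              quad_var_logit(0.25, 0.05), 0.12)
  # monotone in rho, as the quadrature variance is
  e2 <- empirical_random_effect_variance(0.25, 0.10, 1500, 100, seed = 9)
  expect_gt(e2$tau2, e1$tau2)
  expect_gt(quad_var_logit(0.25, 0.10), quad_var_logit(0.25, 0.05))
})
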