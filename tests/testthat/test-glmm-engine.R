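# PQL/REML engine: dense-matrix and brute-force oracles, information
# matrix checks, invariances.

test_that("rank-one-update REML criterion equals the dense-matrix value", {
  f <- small_fit(K = 6, nbar = 8, cv = 0.4, icc = 0.1, seed = 11)
  st <- f$working
  for (th in list(c(0.3, 1), c(0.8, 0.7), c(0.001, 1.3), c(0, 1))) {
    expect_lt(abs(reml_criterion(st, th[1], th[2]) -
                    dense_restricted_ll(st, th[1], th[2])), 1e-10)
  }
})

test_that("blocked fixed-effects covariance equals the dense computation", {
  f <- small_fit(K = 8, nbar = 10, cv = 0.6, icc = 0.05, seed = 21)
  st <- f$working
  th <- st$theta
  expect_lt(max(abs(f$cov_beta - dense_cov_beta(st, th[1], th[2]))), 1e-10)
})

test_that("criterion is invariant to cluster relabeling", {
  f <- small_fit(seed = 31)
  st <- f$working
  perm <- sample(seq_len(nrow(st$Tmat)))
  st2 <- st
  st2$Tmat <- st$Tmat[perm, , drop = FALSE]
  for (fld in c("n", "s", "lw", "m1", "m2")) st2[[fld]] <- st[[fld]][perm]
  expect_equal(reml_criterion(st2, 0.4, 0.9), reml_criterion(st, 0.4, 0.9))
})

test_that("tau2 = 0 collapses the criterion to weighted least squares", {
  f <- small_fit(seed = 41)
  st <- f$working
  # independent-errors restricted likelihood computed directly
  z <- st$z; w <- st$w; X <- st$Tmat[st$cluster, , drop = FALSE]
  XtWX <- t(X) %*% (X * w)
  beta <- solve(XtWX, t(X) %*% (w * z))
  r <- drop(z - X %*% beta)
  ll <- -0.5 * (sum(-log(w)) + determinant(XtWX)$modulus +
                  sum(w * r^2) + (length(z) - 2) * log(2 * pi))
  expect_equal(reml_criterion(st, 0, 1), drop(ll), tolerance = 1e-12)
})

test_that("PQL on iid singleton-cluster data matches plain logistic regression", {
  set.seed(5)
  N <- 400; armv <- rep(0:1, each = N / 2)
  y <- rbinom(N, 1, plogis(-1 + 0.5 * armv))
  d <- crt_data(cluster = 1:N, arm = armv, y = y)
  f <- fit_glmm(d)
  g <- glm(y ~ armv, family = binomial)
  expect_true("degenerate_clusters" %in% f$flags)
  expect_lt(max(abs(f$beta_hat - coef(g)) / abs(coef(g))), 1e-6)
  expect_equal(f$varcomp$tau2, 0)
})

test_that("optimizer tau2 matches a brute-force profiled REML grid search", {
  ctrl <- glmm_control(phi = "fixed")
  sc <- trial_scenario(K = 4, nbar = 6, cv = 0, icc = 0.3, seed = 17)
  f <- fit_glmm(simulate_trial(sc), ctrl)
  st <- f$working
  grid <- seq(0, 5, by = 1e-4)
  vals <- vapply(grid, function(t2) reml_criterion(st, t2, 1), numeric(1))
  expect_lt(abs(f$varcomp$tau2 - grid[which.max(vals)]), 1e-4 + 1e-9)
})

test_that("analytic REML gradient matches finite differences", {
  f <- small_fit(seed = 3)
  st <- f$working
  for (th in list(c(0.4, 0.9), c(0.05, 1.2))) {
    gfd <- pracma::grad(function(x) reml_criterion(st, x[1], x[2]), th)
    expect_lt(max(abs(crtddf:::reml_gradient(st, th[1], th[2]) - gfd) /
                    pmax(abs(gfd), 1e-4)), 1e-5)
  }
})

test_that("gradient vanishes at interior REML optima", {
  f <- small_fit(K = 10, nbar = 30, cv = 0.3, icc = 0.2, seed = 13)
  expect_true(f$converged)
  expect_false(f$boundary)
  g <- crtddf:::reml_gradient(f$working, f$varcomp$tau2, f$varcomp$phi)
  expect_lt(sqrt(sum(g^2)), 1e-5)
})

test_that("observed information equals the finite-difference Hessian", {
  f <- small_fit(seed = 3)
  st <- f$working
  th <- c(0.4, 0.9)
  H <- pracma::hessian(function(x) reml_criterion(st, x[1], x[2]), th)
  Io <- crtddf:::reml_information(st, th[1], th[2], type = "observed")
  expect_lt(max(abs(Io + H) / abs(Io)), 1e-4)
})

test_that("expected and observed information agree on dimensional contracts", {
  f_free <- small_fit(seed = 23)
  expect_identical(dim(varcomp_covariance(f_free)), c(2L, 2L))
  f_fix <- small_fit(seed = 23, control = glmm_control(phi = "fixed"))
  expect_identical(dim(varcomp_covariance(f_fix)), c(1L, 1L))
  A <- varcomp_covariance(f_free)
  expect_equal(A, t(A))
  expect_true(all(eigen(A, symmetric = TRUE)$values > -1e-12))
})

test_that("variance-component uncertainty shrinks like 1/K", {
  vars <- vapply(c(20, 80, 320), function(K) {
    f <- small_fit(K = K, nbar = 30, cv = 0.2, icc = 0.05,
                   seed = 1000 + K)
    varcomp_covariance(f)["tau2", "tau2"]
  }, numeric(1))
  slope <- coef(lm(log(vars) ~ log(c(20, 80, 320))))[2]
  expect_gt(slope, -1.3)
  expect_lt(slope, -0.7)
})

test_that("refits are invariant to cluster relabeling and row permutation", {
  sc <- trial_scenario(K = 8, nbar = 15, cv = 0.5, icc = 0.1, seed = 55)
  d <- simulate_trial(sc)
  f1 <- fit_glmm(d)
  # pure relabeling, same row order: bitwise identical path
  d2 <- crt_data(cluster = letters[d$cluster], arm = d$arm, y = d$y)
  f2 <- fit_glmm(d2)
  expect_lt(max(abs(f1$beta_hat - f2$beta_hat)), 1e-10)
  expect_lt(abs(f1$varcomp$tau2 - f2$varcomp$tau2), 1e-10)
  # row permutation: same fit up to floating-point reduction order
  set.seed(1); perm <- sample(d$N)
  d3 <- crt_data(cluster = d$cluster[perm], arm = d$arm[perm],
                 y = d$y[perm])
  f3 <- fit_glmm(d3)
  expect_lt(max(abs(f1$beta_hat - f3$beta_hat)), 1e-6)
  expect_lt(abs(f1$varcomp$tau2 - f3$varcomp$tau2), 1e-6)
})

test_that("mean tau2-hat is non-decreasing in the generating ICC", {
  mean_tau2 <- function(rho) {
    vals <- vapply(1:30, function(r) {
      sc <- trial_scenario(K = 20, nbar = 40, cv = 0.3, icc = rho,
                           seed = derive_seed(600, r))
      fit_glmm(simulate_trial(sc))$varcomp$tau2
    }, numeric(1))
    mean(vals)
  }
  m <- vapply(c(0.01, 0.05, 0.1), mean_tau2, numeric(1))
  expect_true(all(diff(m) >= 0))
})

test_that("fit validation rejects unusable inputs", {
  d <- simulate_trial(trial_scenario(K = 6, nbar = 10, cv = 0, icc = 0.05,
                                     seed = 1))
  d_one_arm <- crt_data(d$cluster, rep(0L, d$N), d$y)
  expect_error(fit_glmm(d_one_arm), "both arms")
  d_const <- crt_data(d$cluster, d$arm, rep(1L, d$N))
  expect_error(fit_glmm(d_const), "identical")
})
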