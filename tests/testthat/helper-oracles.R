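# Independent oracles used across the suite: dense-matrix REML of the
# working model, quadrature under the Beta law, and small fixture
# builders.  These deliberately avoid the package's rank-one-update code
# paths so they can serve as cross-checks.

# Dense restricted log-likelihood of the working model, from the raw
# working response/weights stored in a fit's working state.
dense_restricted_ll <- function(state, tau2, phi) {
  z <- state$z; w <- state$w; idx <- state$cluster
  X <- state$Tmat[idx, , drop = FALSE]
  N <- length(z); p <- ncol(X)
  Z <- outer(idx, seq_len(nrow(state$Tmat)), `==`) * 1
  V <- tau2 * Z %*% t(Z) + phi * diag(1 / w, N)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% z)
  r <- z - X %*% beta
  drop(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                 t(r) %*% Vi %*% r + (N - p) * log(2 * pi)))
}

# Dense (X' V^-1 X)^-1 from the same raw working data.
dense_cov_beta <- function(state, tau2, phi) {
  z <- state$z; w <- state$w; idx <- state$cluster
  X <- state$Tmat[idx, , drop = FALSE]
  Z <- outer(idx, seq_len(nrow(state$Tmat)), `==`) * 1
  V <- tau2 * Z %*% t(Z) + phi * diag(1 / w, length(z))
  solve(t(X) %*% solve(V) %*% X)
}

# Var(logit p) for p ~ Beta(a, b) matched to (mu, rho), by 1-D quadrature.
quad_var_logit <- function(mu, rho) {
  sh <- beta_shapes(mu, rho)
  f <- function(p) dbeta(p, sh$a, sh$b)
  m <- integrate(function(p) qlogis(p) * f(p), 0, 1, rel.tol = 1e-10)$value
  integrate(function(p) (qlogis(p) - m)^2 * f(p), 0, 1,
            rel.tol = 1e-10)$value
}

# Approximate sampling SD of the ANOVA ICC estimator (balanced-design
# formula with the mean cluster size), used for Monte Carlo tolerances.
icc_sd_approx <- function(rho, nbar, K) {
  sqrt(2 * (1 - rho)^2 * (1 + (nbar - 1) * rho)^2 /
         (nbar * (nbar - 1) * (K - 1)))
}

small_fit <- function(K = 6, nbar = 8, cv = 0.4, icc = 0.1, seed = 11,
                      control = glmm_control()) {
  sc <- trial_scenario(K = K, nbar = nbar, cv = cv, icc = icc, seed = seed)
  fit_glmm(simulate_trial(sc), control)
}

# Synthetic balanced working state (equal cluster sizes, unit weights):
# the normal-response one-way layout where the Satterthwaite DDF has the
# closed-form value K - 2.
balanced_fit <- function(K, n, tau2 = 0.5, phi = 1) {
  Tm <- cbind("(Intercept)" = 1, arm = rep(0:1, each = K / 2))
  st <- list(Tmat = Tm, n = rep(n, K), s = rep(n, K), lw = rep(0, K),
             m1 = rep(0, K), m2 = rep(0, K), N = K * n, p = 2L,
             theta = c(tau2 = tau2, phi = phi), phi_fixed = FALSE,
             method = "REML", info_type = "expected")
  A <- solve(crtddf:::reml_information(st, tau2, phi))
  gs <- crtddf:::gls_state(st, tau2, phi)
  structure(list(working = st, varcomp_cov = A, cov_beta = gs$M,
                 beta_hat = c("(Intercept)" = 0, arm = 0), N = K * n,
                 K = K, rank_X = 2L, converged = TRUE, boundary = FALSE,
                 flags = character(0),
                 varcomp = list(tau2 = tau2, phi = phi)),
            class = "crt_glmm")
}
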