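# PQL / pseudo-likelihood engine for the random-intercept logistic GLMM.
#
# The model is linearized at the current estimates: with eta = X beta + Z b,
# mu = plogis(eta), the working response is z = eta + (y - mu)/(mu(1-mu))
# and the working weight w = mu(1-mu).  Each outer iteration maximizes the
# REML criterion of the working linear mixed model
#     z = X beta + Z b + e,   Var(b) = tau2 I_K,  Var(e) = phi W^{-1},
# over theta = (tau2, phi), then updates beta by generalized least squares
# and b by BLUP.  Because the fixed effects are cluster-constant in a CRT
# (intercept + arm), X restricted to cluster i is 1_{n_i} t_i', and every
# REML quantity reduces to O(K) closed forms through the rank-one
# (compound-symmetry) structure V_i = tau2 * J + phi * W_i^{-1}:
#     V_i^{-1} 1 = w_i / (phi + tau2 s_i),   s_i = sum_j w_ij,
# so no n_i x n_i matrix is ever formed in the hot path.

#' Fitting options for the GLMM engine
#'
#' @param tol convergence tolerance: the outer loop stops when the maximum
#'   relative change in (beta, tau2, phi) falls below `tol`.
#' @param max_iter maximum number of outer linearization iterations.
#' @param method `"REML"` (default) or `"ML"`: whether the variance
#'   components of the working linear mixed model are estimated by
#'   restricted or ordinary (profiled) maximum likelihood.
#' @param phi `"estimate"` (default) to estimate the residual scale of the
#'   working model by REML, or `"fixed"` to hold it at `phi_value`.
#' @param phi_value value of phi when `phi = "fixed"`.
#' @param info information matrix used for the covariance of the variance
#'   components: `"expected"` (Fisher, default) or `"observed"` (negative
#'   Hessian of the REML criterion).
#' @param weight_floor lower clamp for the working weights mu(1-mu);
#'   fits touching the clamp are flagged.
#' @param tau2_init,phi_init starting values for the variance components.
#' @return a list of class `glmm_control`.
#' @export
glmm_control <- function(tol = 1e-8, max_iter = 200L,
                         method = c("REML", "ML"),
                         phi = c("estimate", "fixed"), phi_value = 1,
                         info = c("expected", "observed"),
                         weight_floor = 1e-10,
                         tau2_init = 0.1, phi_init = 1) {
  method <- match.arg(method)
  phi <- match.arg(phi)
  info <- match.arg(info)
  if (phi_value <= 0) stop("`phi_value` must be positive")
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 method = method, phi = phi,
                 phi_value = phi_value, info = info,
                 weight_floor = weight_floor,
                 tau2_init = tau2_init, phi_init = phi_init),
            class = "glmm_control")
}

# Per-cluster sufficient statistics of the working model.  Everything the
# REML criterion, its gradient, the information matrix and the DDF
# machinery need is (n_i, s_i, sum log w, w'z, sum w z^2) plus the
# cluster-level design rows t_i.
working_stats <- function(z, w, cluster, Tmat) {
  K <- nrow(Tmat)
  list(Tmat = Tmat,
       n  = tabulate(cluster, nbins = K),
       s  = rowsum(w, cluster)[, 1],
       lw = rowsum(log(w), cluster)[, 1],
       m1 = rowsum(w * z, cluster)[, 1],
       m2 = rowsum(w * z^2, cluster)[, 1],
       N = length(z), p = ncol(Tmat))
}

# GLS fixed effects and per-cluster residual summaries at theta.
# Returns beta, M = (X'V^-1 X)^-1, and per-cluster h = w'r, q = sum w r^2.
gls_state <- function(st, tau2, phi) {
  g <- phi + tau2 * st$s
  XtViX <- crossprod(st$Tmat, st$Tmat * (st$s / g))
  XtViz <- drop(crossprod(st$Tmat, st$m1 / g))
  M <- solve(XtViX)
  beta <- drop(M %*% XtViz)
  f <- drop(st$Tmat %*% beta)
  list(beta = beta, M = M, XtViX = XtViX, g = g, f = f,
       h = st$m1 - f * st$s,
       q = st$m2 - 2 * f * st$m1 + f^2 * st$s)
}

#' Restricted log-likelihood of the working linear mixed model
#'
#' Evaluates the REML criterion of the working model at given variance
#' components, computed cluster-by-cluster with the rank-one update
#' identity for V_i = tau2 * J + phi * W_i^{-1} (never by dense
#' inversion).  Includes the constant -((N-p)/2) log(2 pi) so the value
#' matches the textbook restricted log-likelihood exactly.
#'
#' @param state a working-model state as stored in `fit$working` of a
#'   [fit_glmm()] result (per-cluster sufficient statistics).
#' @param tau2 random-intercept variance (>= 0).
#' @param phi residual scale of the working model (> 0).
#' @return the restricted log-likelihood (a scalar; larger is better).
#' @export
reml_criterion <- function(state, tau2, phi) {
  pl_criterion(state, tau2, phi, restricted = TRUE)
}

# Profiled pseudo-likelihood criterion of the working model; restricted
# (REML) by default, ordinary profiled ML when restricted = FALSE (the
# log det X'V^-1 X penalty is dropped and the Gaussian constant uses N).
pl_criterion <- function(state, tau2, phi, restricted = TRUE) {
  if (tau2 < 0 || phi <= 0) stop("need tau2 >= 0 and phi > 0")
  gs <- gls_state(state, tau2, phi)
  if (any(gs$g <= 0)) stop("non-positive-definite cluster covariance")
  logdetV <- sum((state$n - 1) * log(phi) - state$lw + log(gs$g))
  rVr <- sum(gs$q / phi - tau2 * gs$h^2 / (phi * gs$g))
  if (restricted) {
    ld_xvx <- determinant(gs$XtViX, logarithm = TRUE)$modulus
    -0.5 * (logdetV + ld_xvx + rVr + (state$N - state$p) * log(2 * pi))
  } else {
    -0.5 * (logdetV + rVr + state$N * log(2 * pi))
  }
}

# Analytic gradient of the (restricted) criterion in theta = (tau2, phi),
# via  dl/dtheta_k = -tr(P Vdot_k)/2 + r'V^-1 Vdot_k V^-1 r / 2,
# with P = V^-1 for profiled ML.
reml_gradient <- function(state, tau2, phi, restricted = TRUE) {
  gs <- gls_state(state, tau2, phi)
  s <- state$s; n <- state$n; g <- gs$g; h <- gs$h; q <- gs$q
  a <- s / g
  tMt <- if (restricted)
    rowSums((state$Tmat %*% gs$M) * state$Tmat) else numeric(length(s))
  trPJ <- sum(a) - sum(tMt * a^2)
  trPW <- sum(n / phi - tau2 * s / (phi * g)) - sum(tMt * s / g^2)
  uJ <- sum((h / g)^2)
  uW <- sum(q / phi^2 - 2 * tau2 * h^2 / (phi^2 * g) +
              tau2^2 * s * h^2 / (phi^2 * g^2))
  c(tau2 = -0.5 * trPJ + 0.5 * uJ,
    phi  = -0.5 * trPW + 0.5 * uW)
}

# REML information matrix in theta = (tau2, phi) (or tau2 alone when phi
# is fixed).  type "expected": I_jk = tr(P Vdot_j P Vdot_k)/2.
# type "observed": -d2 l / dtheta dtheta' =
#   -tr(P Vdot_j P Vdot_k)/2 + r'V^-1 Vdot_j P Vdot_k V^-1 r.
reml_information <- function(state, tau2, phi, type = "expected",
                             phi_fixed = FALSE, restricted = TRUE) {
  gs <- gls_state(state, tau2, phi)
  Tm <- state$Tmat; M <- if (restricted) gs$M else matrix(0, state$p, state$p)
  s <- state$s; n <- state$n; g <- gs$g; h <- gs$h; q <- gs$q
  a <- s / g
  tMt <- rowSums((Tm %*% M) * Tm)
  GJ <- crossprod(Tm, Tm * a^2)
  GW <- crossprod(Tm, Tm * (s / g^2))
  trdd <- function(G1, G2) sum(diag(M %*% G1 %*% M %*% G2))
  tr_JJ <- sum(a^2) - 2 * sum(tMt * a^3) + trdd(GJ, GJ)
  tr_JW <- sum(s / g^2) - 2 * sum(tMt * a^2 / g) + trdd(GJ, GW)
  tr_WW <- sum(n / phi^2 - 2 * tau2 * s / (phi^2 * g) +
                 tau2^2 * s^2 / (phi^2 * g^2)) -
    2 * sum(tMt * s / g^3) + trdd(GW, GW)
  if (type == "expected") {
    I2 <- 0.5 * matrix(c(tr_JJ, tr_JW, tr_JW, tr_WW), 2, 2)
  } else {
    rVr_i <- q / phi - tau2 * h^2 / (phi * g)
    kV_JJ <- sum(h^2 * s / g^3)
    kV_JW <- sum(h^2 / g^3)
    kV_WW <- sum(rVr_i / phi^2 - 2 * tau2 * h^2 / (phi^2 * g^2) +
                   tau2^2 * h^2 * s / (phi^2 * g^3))
    bJ <- drop(crossprod(Tm, h * s / g^2))
    bW <- drop(crossprod(Tm, h / g^2))
    quad <- function(kV, b1, b2) kV - drop(crossprod(b1, M %*% b2))
    I2 <- matrix(c(-0.5 * tr_JJ + quad(kV_JJ, bJ, bJ),
                   -0.5 * tr_JW + quad(kV_JW, bJ, bW),
                   -0.5 * tr_JW + quad(kV_JW, bW, bJ),
                   -0.5 * tr_WW + quad(kV_WW, bW, bW)), 2, 2)
    I2 <- (I2 + t(I2)) / 2
  }
  dimnames(I2) <- list(c("tau2", "phi"), c("tau2", "phi"))
  if (phi_fixed) I2[1, 1, drop = FALSE] else I2
}

# maximize the REML criterion over theta with warm starting
reml_maximize <- function(st, tau2, phi, control) {
  restricted <- control$method == "REML"
  if (control$phi == "fixed") {
    phi <- control$phi_value
    res <- tryCatch(
      optim(par = max(tau2, 0), method = "L-BFGS-B", lower = 0,
            fn = function(t2) -pl_criterion(st, t2, phi, restricted),
            gr = function(t2) -reml_gradient(st, t2, phi, restricted)[1L]),
      error = function(e) NULL)
    if (is.null(res)) return(list(tau2 = tau2, phi = phi, ok = FALSE))
    list(tau2 = res$par, phi = phi, ok = TRUE)
  } else {
    res <- tryCatch(
      optim(par = c(max(tau2, 0), max(phi, 1e-6)), method = "L-BFGS-B",
            lower = c(0, 1e-8),
            fn = function(th) -pl_criterion(st, th[1], th[2], restricted),
            gr = function(th) -reml_gradient(st, th[1], th[2], restricted)),
      error = function(e) NULL)
    if (is.null(res)) return(list(tau2 = tau2, phi = phi, ok = FALSE))
    list(tau2 = res$par[1], phi = res$par[2], ok = TRUE)
  }
}

# Core fitter on an arbitrary cluster-constant design (Tmat: K x p rows
# t_i).  fit_glmm() wraps this with the CRT design (intercept, arm).
fit_glmm_core <- function(y, cluster, Tmat, control = glmm_control()) {
  cluster <- as.integer(cluster)
  K <- nrow(Tmat); p <- ncol(Tmat); N <- length(y)
  flags <- character(0)
  n_i <- tabulate(cluster, nbins = K)
  if (any(n_i < 1L)) stop("every cluster must contain at least one subject")
  degenerate <- all(n_i == 1L)
  if (degenerate) flags <- c(flags, "degenerate_clusters")

  X_full <- Tmat[cluster, , drop = FALSE]
  beta <- suppressWarnings(
    glm.fit(X_full, y, family = binomial())$coefficients)
  if (anyNA(beta)) stop("fixed-effects design is rank deficient")
  b <- numeric(K)
  tau2 <- if (degenerate) 0 else control$tau2_init
  phi <- if (control$phi == "fixed") control$phi_value else control$phi_init
  clamped <- FALSE
  converged <- FALSE
  st <- NULL; gs <- NULL
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    f <- drop(Tmat %*% beta)
    eta <- f[cluster] + b[cluster]
    mu <- plogis(eta)
    w0 <- mu * (1 - mu)
    if (any(w0 < control$weight_floor)) clamped <- TRUE
    w <- pmax(w0, control$weight_floor)
    z <- eta + (y - mu) / w
    st <- working_stats(z, w, cluster, Tmat)
    if (degenerate) {
      gs0 <- gls_state(st, 0, 1)
      tau2_new <- 0
      phi_new <- if (control$phi == "fixed") control$phi_value else
        # closed-form REML (or ML) scale at tau2 = 0
        sum(gs0$q) / (N - if (control$method == "REML") p else 0L)
    } else {
      opt <- reml_maximize(st, tau2, phi, control)
      if (!opt$ok) flags <- c(flags, "optim_error")
      tau2_new <- opt$tau2; phi_new <- opt$phi
    }
    gs <- gls_state(st, tau2_new, phi_new)
    beta_new <- gs$beta
    b_new <- tau2_new * gs$h / gs$g
    delta <- max(abs(c(beta_new - beta, tau2_new - tau2, phi_new - phi)) /
                   (1 + abs(c(beta, tau2, phi))))
    beta <- beta_new; b <- b_new; tau2 <- tau2_new; phi <- phi_new
    if (delta < control$tol) { converged <- TRUE; break }
  }
  mu_fin <- plogis(drop(Tmat %*% beta)[cluster] + b[cluster])
  if (any(mu_fin < 1e-10 | mu_fin > 1 - 1e-10)) {
    flags <- c(flags, "quasi_separation")
    converged <- FALSE
  }
  if (clamped) flags <- c(flags, "weight_clamp")
  if (!converged && !("quasi_separation" %in% flags))
    flags <- c(flags, "non_convergence")
  boundary <- !degenerate && tau2 <= 1e-8
  if (boundary) flags <- c(flags, "tau2_boundary")

  phi_fixed <- control$phi == "fixed"
  info <- tryCatch(
    reml_information(st, tau2, phi, type = control$info,
                     phi_fixed = phi_fixed,
                     restricted = control$method == "REML"),
    error = function(e) NULL)
  A <- NULL
  if (!is.null(info)) {
    ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
    if (all(ev > sqrt(.Machine$double.eps) * max(abs(ev), 1))) {
      A <- solve(info)
    } else {
      A <- MASS::ginv(info)
      flags <- c(flags, "singular_information")
    }
    dimnames(A) <- dimnames(info)
  }
  structure(list(beta_hat = setNames(gs$beta, colnames(Tmat)),
                 cov_beta = gs$M,
                 varcomp = list(tau2 = tau2, phi = phi),
                 varcomp_cov = A,
                 ranef = b,
                 working = c(st, list(z = z, w = w, cluster = cluster,
                                      theta = c(tau2 = tau2, phi = phi),
                                      phi_fixed = phi_fixed,
                                      method = control$method,
                                      info_type = control$info)),
                 converged = converged, n_iter = iter,
                 N = N, K = K, rank_X = p,
                 boundary = boundary, flags = unique(flags)),
            class = "crt_glmm")
}

#' Fit the random-intercept logistic GLMM to a two-arm CRT
#'
#' Pseudo-likelihood (PQL-type) fit: the binary GLMM is iteratively
#' linearized into a working linear mixed model whose variance components
#' (random-intercept variance tau2 and residual scale phi) are estimated
#' by REML at each step; fixed effects are updated by generalized least
#' squares and random effects by BLUP.  The returned covariance of the
#' fixed effects is the model-based (X' V^-1 X)^-1 at the final estimates,
#' and the covariance of the variance-component estimates is the inverse
#' REML information, as required by the Satterthwaite and Kenward-Roger
#' degrees-of-freedom approximations.
#'
#' If every cluster has exactly one subject the random intercept is
#' unidentifiable; the engine then fixes tau2 = 0 (flag
#' `"degenerate_clusters"`) and the fit reduces to ordinary iteratively
#' reweighted least squares for logistic regression.
#'
#' @param data a [crt_data()] object (or anything [crt_data()] accepts via
#'   a data frame with columns cluster, arm, y).
#' @param control a [glmm_control()] list.
#' @return an object of class `crt_glmm` with elements `beta_hat`
#'   (intercept and arm effect), `cov_beta`, `varcomp` (`tau2`, `phi`),
#'   `varcomp_cov`, `ranef`, `working` (final working-model state),
#'   `converged`, `n_iter`, `N`, `K`, `rank_X`, `boundary` and `flags`.
#' @export
fit_glmm <- function(data, control = glmm_control()) {
  if (is.data.frame(data)) data <- crt_data(data$cluster, data$arm, data$y)
  stopifnot(inherits(data, "crt_data"))
  if (length(unique(data$cluster_arm)) < 2L)
    stop("both arms must be present in the data")
  if (all(data$y == data$y[1L]))
    stop("outcomes are all identical; the model is not estimable")
  if (data$N < 3L) stop("too few subjects to fit the model")
  Tmat <- cbind("(Intercept)" = 1, arm = data$cluster_arm)
  fit <- fit_glmm_core(data$y, data$cluster, Tmat, control)
  fit$cluster_sizes <- data$cluster_sizes
  fit
}

#' Covariance of the variance-component estimates
#'
#' Inverse of the REML information matrix in theta = (tau2, phi) at the
#' fitted values (1 x 1 if phi was fixed).  The expected (Fisher)
#' information is the default; the observed information (negative Hessian
#' of the restricted log-likelihood) is available via `type`.  A singular
#' information matrix (e.g. tau2 at the zero boundary with a flat
#' profile) is pseudo-inverted and flagged via attribute `"singular"`.
#'
#' @param fit a converged [fit_glmm()] result.
#' @param type `"expected"` or `"observed"`; defaults to the type used at
#'   fit time.
#' @return the covariance matrix A of theta-hat.
#' @export
varcomp_covariance <- function(fit, type = NULL) {
  stopifnot(inherits(fit, "crt_glmm"))
  st <- fit$working
  type <- type %||% st$info_type
  info <- reml_information(st, st$theta[["tau2"]], st$theta[["phi"]],
                           type = type, phi_fixed = st$phi_fixed,
                           restricted = st$method == "REML")
  ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
  if (all(ev > sqrt(.Machine$double.eps) * max(abs(ev), 1))) {
    A <- solve(info)
    attr(A, "singular") <- FALSE
  } else {
    A <- MASS::ginv(info)
    attr(A, "singular") <- TRUE
  }
  dimnames(A) <- dimnames(info)
  A
}

#' @export
print.crt_glmm <- function(x, ...) {
  cat("Random-intercept logistic GLMM (PQL / REML working model)\n")
  cat(sprintf("  N = %d subjects, K = %d clusters; %s in %d iterations\n",
              x$N, x$K,
              if (x$converged) "converged" else "DID NOT CONVERGE",
              x$n_iter))
  est <- cbind(Estimate = x$beta_hat, SE = sqrt(diag(x$cov_beta)))
  print(round(est, 4))
  cat(sprintf("  tau2 = %.4f, phi = %.4f%s\n", x$varcomp$tau2,
              x$varcomp$phi,
              if (x$boundary) " (tau2 at boundary)" else ""))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
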