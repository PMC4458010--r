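# Wald chi-square / F statistics and the five denominator-degrees-of-
# freedom (DDF) approximations for the intervention-effect test in a CRT.
#
# Residual, Containment and Between-Within are design-based counting
# rules (N - rank X, N - K, K - rank X).  Satterthwaite moment-matches
# the contrast variance: d = 2 (L V L')^2 / Var[L V L'], with Var[.]
# obtained by the multivariate delta method over the REML
# variance-component covariance.  Kenward-Roger inflates the fixed-effects
# covariance for variance-component uncertainty; for rank-1 contrasts its
# DDF equals the Satterthwaite DDF and the inflation enters as the scale
# of the F statistic.

check_contrast <- function(L, p) {
  if (is.matrix(L)) {
    if (nrow(L) > 1L)
      stop("multi-row contrasts (r > 1) are not supported; ",
           "the Wald F test implemented here is single-degree-of-freedom")
    L <- drop(L)
  }
  if (length(L) != p) stop("contrast length must match the number of fixed effects")
  if (all(L == 0)) stop("contrast must be non-zero")
  L
}

#' Residual denominator degrees of freedom: N - rank(X)
#' @param N total number of subjects.
#' @param rank_X rank of the fixed-effects design (2 for a two-arm CRT).
#' @return the DDF, `N - rank_X`.
#' @export
ddf_residual <- function(N, rank_X = 2L) {
  d <- N - rank_X
  if (d <= 0) stop("non-positive residual DDF: N must exceed rank(X)")
  d
}

#' Containment denominator degrees of freedom: N - K
#'
#' For a cluster-constant treatment effect with a single cluster random
#' intercept, the containment rule reduces to total subjects minus total
#' clusters.
#' @param N total number of subjects.
#' @param K number of clusters.
#' @return the DDF, `N - K`.
#' @export
ddf_containment <- function(N, K) {
  d <- N - K
  if (d <= 0) stop("non-positive containment DDF: N must exceed K ",
                   "(all-singleton clusters cannot support this test)")
  d
}

#' Between-Within denominator degrees of freedom: K - rank(X)
#'
#' A cluster-constant fixed effect receives the between-cluster portion
#' of the residual degrees of freedom.
#' @param K number of clusters.
#' @param rank_X rank of the fixed-effects design.
#' @return the DDF, `K - rank_X`.
#' @export
ddf_between_within <- function(K, rank_X = 2L) {
  d <- K - rank_X
  if (d <= 0) stop("non-positive between-within DDF: need more clusters ",
                   "than fixed effects")
  d
}

# Contrast variance Phi(theta) = L (X'V^-1 X)^-1 L' and its analytic
# gradient in theta = (tau2, phi), using
#   d(X'V^-1X)^-1/dtheta_k = M (X'V^-1 Vdot_k V^-1 X) M
# with X'V^-1 J V^-1 X = sum t_i a_i^2 t_i',  a_i = s_i/g_i, and
# X'V^-1 W^-1 V^-1 X = sum t_i (s_i/g_i^2) t_i'.
satt_components <- function(fit, L = c(0, 1)) {
  st <- fit$working
  L <- check_contrast(L, st$p)
  tau2 <- st$theta[["tau2"]]; phi <- st$theta[["phi"]]
  gs <- gls_state(st, tau2, phi)
  Tm <- st$Tmat
  a <- st$s / gs$g
  GJ <- crossprod(Tm, Tm * a^2)
  GW <- crossprod(Tm, Tm * (st$s / gs$g^2))
  ML <- drop(gs$M %*% L)
  Phi <- drop(crossprod(L, ML))
  grad <- c(tau2 = drop(crossprod(ML, GJ %*% ML)),
            phi  = drop(crossprod(ML, GW %*% ML)))
  if (st$phi_fixed) grad <- grad[1L]
  A <- fit$varcomp_cov
  if (is.null(A)) stop("fit carries no variance-component covariance")
  varPhi <- drop(crossprod(grad, A %*% grad))
  list(Phi = Phi, grad = grad, A = A, varPhi = varPhi,
       M = gs$M, GJ = GJ, GW = GW, tau2 = tau2, phi = phi)
}

#' Satterthwaite denominator degrees of freedom (delta method)
#'
#' For a rank-1 contrast, d = 2 (L V-hat L')^2 / Var[L V-hat L'], where
#' the variance of the estimated contrast variance is approximated by the
#' multivariate delta method: Var = g' A g with g the analytic gradient
#' of the contrast variance in (tau2, phi) and A the inverse REML
#' information from [varcomp_covariance()].
#'
#' @param fit a [fit_glmm()] result.
#' @param L contrast vector (default `c(0, 1)`: the arm effect).
#' @return the DDF `d` (uncapped), with attribute `"flags"`: character
#'   vector possibly containing `"exceeds_N"` (d > N), `"known_varcomp"`
#'   (zero delta-method variance, d = Inf) or `"failed"` (negative
#'   delta-method variance; d is NA and the method is unusable on this
#'   fit).
#' @export
ddf_satterthwaite <- function(fit, L = c(0, 1)) {
  sc <- satt_components(fit, L)
  flags <- character(0)
  if (sc$varPhi < 0) {
    d <- NA_real_; flags <- "failed"
  } else if (sc$varPhi == 0) {
    d <- Inf; flags <- "known_varcomp"
  } else {
    d <- 2 * sc$Phi^2 / sc$varPhi
    if (d > fit$N) flags <- "exceeds_N"
  }
  structure(d, flags = flags)
}

#' Kenward-Roger adjusted covariance, scale and DDF
#'
#' Small-sample adjustment of the fixed-effects covariance for
#' variance-component uncertainty, in the standard two-term form
#' `Phi_A = M + 2 M (sum_jk A_jk (Q_jk - P_j M P_k)) M` (the term in
#' second derivatives of V vanishes because V is linear in (tau2, phi)).
#' Because the intervention-effect contrast has rank 1, the DDF equals
#' the Satterthwaite DDF computed from the unadjusted covariance, and the
#' adjustment enters through the scale `phi_scale = (L Phi_A L')/(L M L')
#' >= 1`: the scaled statistic is F = T2 / phi_scale, i.e. the squared
#' estimate over the inflated variance.
#'
#' @inheritParams ddf_satterthwaite
#' @return a list with `cov_adj` (adjusted covariance of beta-hat),
#'   `se_adj` (adjusted SE of the contrast), `phi_scale`, `d` (the
#'   Satterthwaite DDF), and `flags`.
#' @export
kr_adjusted <- function(fit, L = c(0, 1)) {
  sc <- satt_components(fit, L)
  st <- fit$working
  L <- check_contrast(L, st$p)
  M <- sc$M; A <- sc$A
  tau2 <- sc$tau2; phi <- sc$phi
  gs <- gls_state(st, tau2, phi)
  Tm <- st$Tmat; s <- st$s; g <- gs$g
  a <- s / g
  # Q_jk = X'V^-1 Vdot_j V^-1 Vdot_k V^-1 X, cluster-blockwise scalars
  Q <- list(tau2 = list(tau2 = crossprod(Tm, Tm * a^3),
                        phi  = crossprod(Tm, Tm * (a^2 / g))),
            phi  = list(tau2 = crossprod(Tm, Tm * (a^2 / g)),
                        phi  = crossprod(Tm, Tm * (s / g^3))))
  P <- list(tau2 = sc$GJ, phi = sc$GW)
  comps <- if (st$phi_fixed) "tau2" else c("tau2", "phi")
  S <- matrix(0, st$p, st$p)
  for (j in comps) for (k in comps)
    S <- S + A[j, k] * (Q[[j]][[k]] - P[[j]] %*% M %*% P[[k]])
  cov_adj <- M + 2 * M %*% S %*% M
  cov_adj <- (cov_adj + t(cov_adj)) / 2
  v_unadj <- sc$Phi
  v_adj <- drop(crossprod(L, cov_adj %*% L))
  flags <- attr(ddf_satterthwaite(fit, L), "flags")
  if (v_adj < v_unadj) {
    # the two-term correction is non-negative for linear covariance
    # structures up to rounding; clamp tiny negative excursions
    if (v_adj < v_unadj * (1 - 1e-8)) flags <- c(flags, "deflated_covariance")
    v_adj <- max(v_adj, v_unadj)
  }
  d <- as.numeric(ddf_satterthwaite(fit, L))
  list(cov_adj = cov_adj, se_adj = sqrt(v_adj),
       phi_scale = v_adj / v_unadj, d = d, flags = unique(flags))
}

#' Wald chi-square statistic for a rank-1 contrast
#'
#' T2 = (L beta-hat)' (L cov L')^-1 (L beta-hat); for a single-row
#' contrast this is simply (estimate / SE)^2.
#'
#' @param beta_hat fixed-effects estimate vector.
#' @param cov covariance matrix of `beta_hat`.
#' @param L contrast vector.
#' @return the chi-square statistic (>= 0).
#' @export
wald_chi2 <- function(beta_hat, cov, L = c(0, 1)) {
  L <- check_contrast(L, length(beta_hat))
  v <- drop(crossprod(L, cov %*% L))
  if (v <= 0) stop("non-positive contrast variance")
  drop(crossprod(L, beta_hat))^2 / v
}

#' Wald F test from a chi-square statistic and a DDF
#'
#' F = T2 / (phi_scale * r) referred to an F distribution with
#' (r, d) degrees of freedom; the p-value is the upper tail.
#'
#' @param T2 Wald chi-square statistic.
#' @param r numerator degrees of freedom (only r = 1 is supported).
#' @param d denominator degrees of freedom (> 0).
#' @param phi_scale scale of the statistic (1 except for Kenward-Roger).
#' @return a list with `F`, `ddf` and `p_value`.
#' @export
wald_f_test <- function(T2, r = 1L, d, phi_scale = 1) {
  if (r != 1L) stop("only single-degree-of-freedom tests (r = 1) are supported")
  if (is.na(d) || d <= 0) stop("invalid denominator degrees of freedom")
  if (phi_scale <= 0) stop("`phi_scale` must be positive")
  Fv <- T2 / (phi_scale * r)
  list(F = Fv, ddf = d, p_value = pf(Fv, r, d, lower.tail = FALSE))
}

#' All five DDF-based Wald F tests on one fitted GLMM
#'
#' Computes the intervention-effect Wald F test under the Residual,
#' Containment, Between-Within, Satterthwaite and Kenward-Roger DDF
#' approximations.  The first three share the identical F statistic and
#' differ only in the DDF; Kenward-Roger additionally inflates the
#' standard error (so its F is smaller) while sharing the Satterthwaite
#' DDF.
#'
#' @param fit a [fit_glmm()] result.
#' @param L contrast vector (default the arm effect).
#' @param methods subset of
#'   `c("residual", "containment", "between_within", "satterthwaite",
#'   "kenward_roger")`.
#' @return a data frame with one row per method: `method`, `estimate`,
#'   `se`, `F`, `num_df`, `ddf`, `phi_scale`, `p_value`, `ok` (logical:
#'   the method produced a usable test on this fit) and `flags`.
#' @export
wald_tests <- function(fit, L = c(0, 1),
                       methods = c("residual", "containment",
                                   "between_within", "satterthwaite",
                                   "kenward_roger")) {
  stopifnot(inherits(fit, "crt_glmm"))
  methods <- match.arg(methods, several.ok = TRUE)
  L <- check_contrast(L, fit$rank_X)
  est <- drop(crossprod(L, fit$beta_hat))
  se <- sqrt(drop(crossprod(L, fit$cov_beta %*% L)))
  T2 <- wald_chi2(fit$beta_hat, fit$cov_beta, L)
  rows <- lapply(methods, function(m) {
    flags <- character(0); ok <- TRUE
    phi_scale <- 1; se_m <- se
    d <- switch(m,
      residual = tryCatch(ddf_residual(fit$N, fit$rank_X),
                          error = function(e) NA_real_),
      containment = tryCatch(ddf_containment(fit$N, fit$K),
                             error = function(e) NA_real_),
      between_within = tryCatch(ddf_between_within(fit$K, fit$rank_X),
                                error = function(e) NA_real_),
      satterthwaite = {
        ds <- ddf_satterthwaite(fit, L)
        flags <- c(flags, attr(ds, "flags"))
        as.numeric(ds)
      },
      kenward_roger = {
        kr <- kr_adjusted(fit, L)
        flags <- c(flags, kr$flags)
        phi_scale <- kr$phi_scale
        se_m <- kr$se_adj
        kr$d
      })
    if (is.na(d) || !is.finite(d) || d <= 0) {
      ok <- FALSE
      res <- list(F = NA_real_, p_value = NA_real_)
      if (!length(flags)) flags <- "invalid_ddf"
    } else {
      res <- wald_f_test(T2, r = 1L, d = d, phi_scale = phi_scale)
    }
    data.frame(method = m, estimate = est, se = se_m,
               F = res$F, num_df = 1L, ddf = d, phi_scale = phi_scale,
               p_value = res$p_value, ok = ok,
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
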