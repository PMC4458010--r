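---
title: "Small-sample Wald F inference for cluster-randomized trials with binary outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-sample Wald F inference for cluster-randomized trials with binary outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtddf)
```

## The problem

In a cluster-randomized trial (CRT) intact groups — practices, wards,
schools — are randomized to arms, so outcomes of subjects in the same
cluster are positively correlated (intraclass correlation, ICC).  With a
binary outcome the standard individual-level analysis is a logistic
generalized linear mixed model (GLMM) with a cluster random intercept:

$$\mathrm{logit}\, P(y_{ij} = 1 \mid b_i) = \alpha + \beta x_i + b_i,
\qquad b_i \sim N(0, \tau^2),$$

with $x_i \in \{0, 1\}$ the arm of cluster $i = 1, \dots, K$ and
$j = 1, \dots, n_i$ indexing subjects.  The intervention effect is tested
with a Wald statistic $T^2 = (\hat\beta / \widehat{\mathrm{se}})^2$,
referred to an $F_{1,d}$ distribution.  With few clusters the choice of
the denominator degrees of freedom $d$ (DDF) dominates the operating
characteristics of the test: too large a $d$ gives a liberal test, too
small a conservative one.  This package implements the five DDF rules in
common use and the simulation machinery to measure their type I error
and power:

| method          | $d$                         |
|-----------------|-----------------------------|
| Residual        | $N - \mathrm{rank}(X)$      |
| Containment     | $N - K$                     |
| Between-Within  | $K - \mathrm{rank}(X)$      |
| Satterthwaite   | estimated from the data     |
| Kenward-Roger   | estimated from the data     |

where $N = \sum_i n_i$ and $\mathrm{rank}(X) = 2$ (intercept and arm).

## Estimation: pseudo-likelihood with REML

`fit_glmm()` fits the model by iterative linearization
(penalized quasi-likelihood / pseudo-likelihood).  At the current
estimates, with $\eta = X\beta + Zb$ and $\mu = \mathrm{logistic}(\eta)$,
the working response is $z = \eta + (y - \mu) / (\mu(1 - \mu))$ with
weight $w = \mu(1-\mu)$, and the working linear mixed model

$$z = X\beta + Zb + e, \qquad \mathrm{Var}(b) = \tau^2 I_K, \quad
\mathrm{Var}(e) = \phi W^{-1}$$

is fitted by REML over $(\tau^2, \phi)$, followed by generalized least
squares for $\beta$ and BLUP for $b$, until the largest relative change
in $(\beta, \tau^2, \phi)$ falls below $10^{-8}$ (at most 200 outer
iterations).  This is the scheme whose DDF machinery the five rules were
designed around: the Satterthwaite and Kenward-Roger quantities are
defined on the working linear mixed model.  Adaptive-quadrature maximum
likelihood is deliberately out of scope; `glmm_control(method = "ML")`
switches the working-model variance estimation from REML to profiled ML
for sensitivity analyses.

Because both fixed effects are constant within cluster, every REML
quantity reduces to closed forms in per-cluster summaries through the
compound-symmetry identity
$V_i^{-1}\mathbf{1} = w_i / (\phi + \tau^2 s_i)$, $s_i = \sum_j w_{ij}$,
so no dense matrix is formed; fits cost microseconds per iteration even
for hundreds of clusters.

Tunable parameters and defaults:

* `phi` (residual scale of the working model): estimated by default.  A
  free scale accommodates the over/under-dispersion that motivates the F
  (rather than chi-square) test; `phi = "fixed"` pins it at 1.
* `tau2_init = 0.1`, `phi_init = 1`: starting values; the REML surface
  here is one- or two-dimensional and benign, so initialization only
  affects speed.
* Working weights are floored at `1e-10` and fits touching the floor are
  flagged, as are quasi-separated fits (fitted probabilities within
  `1e-10` of 0 or 1).
* $\hat\tau^2$ is constrained to $[0, \infty)$; estimates at the zero
  boundary are kept (flag `tau2_boundary`), and a singular
  variance-component information matrix is pseudo-inverted rather than
  failing the fit.
* If every cluster is a singleton the random intercept is
  unidentifiable; the engine fixes $\tau^2 = 0$ (flag
  `degenerate_clusters`), which makes the fit collapse exactly to
  ordinary logistic regression.

The covariance of $(\hat\tau^2, \hat\phi)$ — the input to the
Satterthwaite and Kenward-Roger approximations — is the inverse REML
information.  The *expected* (Fisher) information is the default; the
*observed* information (negative Hessian of the restricted
log-likelihood) is available via `glmm_control(info = "observed")`.  The
two differ at finite samples; expected information is the conventional
choice in mixed-model software and is what the package's operating
characteristics below are computed with.

## The two data-driven DDF rules

For the rank-1 arm contrast $L = (0, 1)$ the Satterthwaite DDF is

$$d = \frac{2\,(L \hat V(\hat\beta) L')^2}{\mathrm{Var}[L \hat V(\hat\beta) L']},$$

with the denominator obtained by the multivariate delta method:
$\mathrm{Var}[\cdot] = g' A g$, where $g$ is the analytic gradient of the
contrast variance in $(\tau^2, \phi)$ and $A$ the variance-component
covariance above.  On a balanced one-way layout this reproduces the
classical $K - 2$ exactly, which the test suite checks.

Kenward-Roger adjusts the fixed-effects covariance for
variance-component uncertainty with the standard two-term correction
$\Phi_A = M + 2M\{\sum_{jk} A_{jk}(Q_{jk} - P_j M P_k)\}M$ (the term in
second derivatives of $V$ vanishes because $V$ is linear in
$(\tau^2,\phi)$).  For a rank-1 contrast the Kenward-Roger DDF equals
the Satterthwaite DDF computed from the *unadjusted* covariance, and the
adjustment enters as the scale
$\varphi = (L\Phi_A L')/(LML') \ge 1$ of the statistic:
$F = T^2/\varphi$, i.e. the squared estimate over the inflated variance.
This is the only reading consistent with reporting the same DDF but a
larger standard error (and hence smaller $F$ and larger $p$) for
Kenward-Roger than for Satterthwaite on the same fit.

## The trial simulator

`simulate_trial()` generates two-arm CRTs with the beta-binomial
correlation structure: each cluster draws its event probability from
$\mathrm{Beta}(a, b)$ with $a = \mu(1-\rho)/\rho$,
$b = (1-\mu)(1-\rho)/\rho$, so the marginal event proportion is $\mu$
and the ICC is $\rho$; outcomes are iid Bernoulli given the cluster
probability.  Cluster sizes are drawn from
$N(\bar n, \bar n^2\,\mathrm{cv}^2)$, rounded, and clamped below at 1.
Defaults mirror a realistic small CRT: control-arm proportion
$\mu_0 = 0.25$, ICC in the range 0.001–0.1, 10–30 clusters of 20–100
subjects on average, cv of cluster sizes between 0 and 1.  Design
choices worth noting:

* The intervention arm applies the odds ratio on the *marginal* scale
  ($\mu_1 = \mathrm{OR}\cdot\mathrm{odds}(\mu_0)$ mapped back to a
  proportion; $\mu_1 = 1/3$ for $\mu_0 = 0.25$, OR 1.5), because the
  beta-binomial generator only controls marginal moments.  The
  conditional (GLMM-scale) odds ratio is attenuated relative to this
  marginal one; `simulate_glmm_trial()` generates directly from the
  conditional model when the conditional parameter is the estimand.
* Clamping cluster sizes at 1 slightly raises the realized mean size at
  cv near 1; this is accepted (and measured in the tests) rather than
  re-normalized away.
* Arm assignment is deterministic — first $K/2$ clusters control — since
  randomizing labels has no distributional effect in this setting.
* Every replicate derives its own seed from the master seed by a
  counter scheme (`derive_seed()`), so any single replicate can be
  regenerated in isolation.

The latent logit-scale variance implied by $(\mu, \rho)$ has no closed
form.  By numerical quadrature of $\mathrm{Var}(\mathrm{logit}\,p)$
under the Beta law, $\mu = 0.25$ and $\rho \in \{0.001, 0.01, 0.05,
0.1\}$ imply $\tau^2 \approx \{0.005, 0.055, 0.31, 0.72\}$;
`empirical_random_effect_variance()` reports the corresponding fitted
diagnostic, which sits a few percent below the quadrature value at the
larger ICCs because the pseudo-likelihood linearization attenuates
$\hat\tau^2$ slightly.

## The Monte Carlo study driver

`run_type1()` / `run_power()` simulate a scenario `n_reps` times, fit
each replicate, test the arm effect with every requested DDF method at
two-sided $\alpha = 0.05$ via the upper F tail, and report the rejection
fraction among converged fits.  A rate is classified against the
nominal band $\alpha \pm 1.96\sqrt{\alpha(1-\alpha)/n}$ (rounded to 3
decimals; $[0.044, 0.056]$ at $n = 5000$): below it *conservative*,
above it *liberal*, inside it *nominal*.  Replicates whose fit fails to
converge — or, for the data-driven rules, whose delta-method variance is
not positive — are excluded from that method's denominator and counted
in a failure column; a scenario with more than 5% failures is flagged
unreliable.  `run_grid()` crosses the scenario axes (the full published
grid is $3 \times 3 \times 5 \times 4 = 180$ scenarios) with derived
per-scenario seeds and returns a long results table.

## What a run shows

The package's own acceptance runs (5000 null replicates per scenario,
problem sizes chosen to keep a full run in minutes on one CPU) reproduce
the qualitative small-sample picture:

* **Residual / Containment** are liberal with $K = 10$ heterogeneous
  clusters (observed rates near 0.065–0.07).
* **Satterthwaite / Kenward-Roger** are conservative there, more so as
  cv grows (rates near 0.02–0.03 at cv = 0.8), with Kenward-Roger the
  more conservative of the two.
* **Between-Within** sits between those extremes everywhere and is the
  only rule whose rate stays close to nominal across the grid; in our
  runs it is within the band at ICC $\ge$ 0.05 and modestly below it in
  the low-ICC corner (see limitations).
* Under the alternative (OR 1.5) Between-Within is at least as powerful
  as Kenward-Roger, markedly so with heterogeneous cluster sizes.

## Numerical choices

* REML maximization: bounded quasi-Newton (L-BFGS-B) on
  $(\tau^2, \phi)$ with analytic gradients, warm-started across outer
  iterations; lower bounds $0$ and $10^{-8}$.
* Per-cluster covariance inversion uses the rank-one update identity
  throughout; the dense computation exists only in the test suite as an
  oracle.
* Ties and degenerate inputs: non-positive DDFs raise errors
  (e.g. Containment with all-singleton clusters); a zero Wald statistic
  gives $p = 1$; multi-row contrasts are rejected as unsupported because
  the intervention test has one numerator degree of freedom.
* Reported tables round to 4 decimals; all stored values are full
  precision.

## Limitations

* Pseudo-likelihood linearization attenuates $\hat\tau^2$ by a few
  percent at moderate cluster sizes; parameter-recovery runs at
  $K = 400$, $n_i = 50$, $\tau^2 = 0.44$ show a mean shortfall of about
  2%, of the same order as the Monte Carlo uncertainty of a 200-replicate
  experiment.
* In the low-ICC, small-$K$ corner (ICC $\approx 0.01$, $K = 10$,
  $\bar n = 50$) the Between-Within test is mildly conservative under
  this estimation scheme (observed rate $\approx$ 0.034 at cv = 0.5)
  even though its standard error is, on average, perfectly calibrated.
  The mechanism: with the between-cluster variance only about a third of
  $\mathrm{Var}(\hat\beta)$ and $\hat\tau^2$ bounded at zero, the
  estimated standard error lacks the $\chi^2_{K-2}$-type variability
  that would make the statistic genuinely $t_{K-2}$; the same test is
  within the nominal band at ICC 0.05.  An independent Laplace-ML fitter
  shows the same depression, so this is a property of bounded
  variance-component estimation in this corner, not of the
  linearization.
* The simulator emulates exchangeable within-cluster correlation with
  cluster-constant covariates only.  Real trials with subject-level
  covariates, non-exchangeable correlation (e.g. longitudinal CRTs), or
  informative cluster sizes are outside what passing tests demonstrate.
* Only the logit link and a single random intercept (compound symmetry)
  are supported; likelihood-ratio and multi-row Wald tests are
  non-goals.
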