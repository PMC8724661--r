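---
title: "Quantile linear mixed models via SAEM: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile linear mixed models via SAEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

For longitudinal data with subjects $i = 1, \dots, n$ observed at occasions
$j = 1, \dots, n_i$, the package models the conditional $\tau$-th quantile of
a continuous response as

$$Q_\tau(y_{ij} \mid x_{ij}, b_i) = x_{ij}'\beta_\tau + z_{ij}'b_i,
\qquad b_i \sim N_r(0, \Psi),$$

with fixed effects $\beta_\tau$ specific to the quantile level
$\tau \in (0,1)$ and Gaussian subject-level random effects $b_i$ inducing
the within-subject dependence.  Estimation is likelihood-based: the error
$\varepsilon_{ij} = y_{ij} - x_{ij}'\beta_\tau - z_{ij}'b_i$ is assigned the
asymmetric Laplace distribution (ALD)

$$f(\varepsilon) = \frac{\tau(1-\tau)}{\sigma}
  \exp\!\left\{-\rho_\tau\!\left(\frac{\varepsilon}{\sigma}\right)\right\},
\qquad \rho_\tau(u) = u\,(\tau - I\{u < 0\}),$$

whose $\tau$-quantile is exactly zero, so the quantile restriction is built
into the error law.  Maximizing the ALD likelihood in $\beta_\tau$ is
equivalent to minimizing the check-loss criterion of classical quantile
regression; the ALD is a working likelihood that makes mixed-effects
machinery (random effects, information criteria, likelihood ratios)
available at any quantile level.  `ald_logpdf()`, `ald_cdf()`,
`ald_quantile()` and `ald_sample()` expose the distribution;
`check_loss()` is the loss itself.

The motivating application is immune-marker trajectories in treated HIV
cohorts: square-root CD4 count as the response; months since enrollment and
its square root as population slopes; baseline BMI, log baseline viral
load, baseline age, and a pre/post antiretroviral-therapy indicator as
covariates; and a random intercept plus random time and square-root-time
slopes per patient.  That seven-term fixed / three-term random structure is
the package default (`model_spec()`), but any subset of the vocabulary can
be requested.

One modeling decision deserves a note.  The therapy indicator is treated as
**time-varying within subject** (0 before the initiation month, 1 after),
because patients initiate therapy during follow-up and the scientific
question is the within-patient response to treatment.  Baseline BMI, log
viral load and age are per-subject constants replicated across visits.

## Why SAEM

The marginal likelihood integrates the random effects against a
non-differentiable integrand, so neither the E-step of classical EM nor the
integral itself is available in closed form.  The package uses the
stochastic approximation EM (SAEM) algorithm: each iteration simulates the
random effects from their conditional distribution, smooths simulated
quantities across iterations, and maximizes the smoothed complete-data
likelihood.  Compared with Monte Carlo EM, SAEM reuses simulations across
iterations and converges with a small, fixed simulation size per iteration
(the package default keeps $m \le 20$ draws per subject).

The smoothing weights follow the two-phase schedule

$$\delta_k = \begin{cases} 1 & 1 \le k \le cW\\
\min\{1, 1/(k - cW)\} & cW < k \le W, \end{cases}$$

where $c \in (0,1)$ sets the fraction of memory-free burn-in iterations and
$W$ caps the iteration count.  During the memory phase the accumulator is
exactly the current batch (each iteration is a Monte Carlo EM step); after
the cut, batches are averaged with decaying influence.  The clamp to 1 just
past a non-integer cut point keeps the schedule a nonincreasing sequence of
weights.  Defaults: `c = 0.25`, `W = 500`, `m = 20` — deliberately
conservative and always overridable through `saem_config()`.

### E-step: Metropolis–Hastings

The conditional density of $b_i$ is log-concave but nonstandard, so the
package simulates it with a random-walk Metropolis–Hastings chain whose
proposal is $N(b, s^2 \Psi_k)$, warm-started at the subject's final draw of
the previous iteration (this is what makes reusing simulations effective).
Each iteration discards `burn_in` steps (default 10) and keeps `m` draws.
The global proposal factor $s$ is adapted during the memory phase toward a
20–40% acceptance rate, then frozen so the post-memory chain is a fixed
Markov kernel.  Acceptance rates are recorded per iteration in the fit
traces.

### The stochastic approximation

The check loss admits no finite-dimensional sufficient statistics, so the
smoothed complete-data criterion is carried through a **weighted draw
pool**: historical draws keep weight $w(1-\delta_k)$, the $m$ new draws per
subject enter with weight $\delta_k/m$, and entries whose weight falls
below `pool_weight_floor` (default $10^{-4}$) are pruned.  For the Gaussian
part, per-subject second moments are smoothed elementwise — these *are*
sufficient for $\Psi$.  With the reciprocal-decay schedule all post-memory
batches end up equally weighted, so the pool grows linearly in iterations;
the M-step kernel exploits the fact that all pool entries share one design
matrix, so memory and time stay proportional to $N \times$ (pool draws)
rather than requiring a materialized stacked design.

### M-step

Given the pool, the three blocks maximize in closed form or by convex
optimization:

* $\beta$: pool-weighted check-loss regression on the pseudo-responses
  $y_{ij} - z_{ij}'b^{(d)}_i$, solved by the interior point method below
  (`mstep_beta()`);
* $\sigma$: the pool-weighted mean per-observation check loss — the exact
  stationary point of the ALD likelihood at fixed residuals
  (`mstep_sigma()`);
* $\Psi$: the average of the smoothed second moments, symmetrized, with
  eigenvalues floored at $10^{-8}$ (`mstep_psi()`).

Each M-step can only improve the pooled complete-data objective; the fit
traces record the objective before and after every M-step and the test
suite asserts the improvement at every iteration.

### Initialization and convergence

$\beta^{(0)}$ is the fixed-effects-only check regression, $\sigma^{(0)}$
the mean check loss of its residuals, and
$\Psi^{(0)} = 0.1\,\sigma_0^2 I_r$.  Scaling the initialization with
$\sigma_0^2$ makes the entire algorithm equivariant: adding a constant to
all responses shifts only the intercept, and rescaling the responses by
$s > 0$ rescales $\hat\beta$ and $\hat\sigma$ by $s$ — properties the test
suite checks on full fits.

The run stops early when the maximum relative parameter change stays below
`convergence_tol` (default $10^{-4}$) for `convergence_window` (default 10)
consecutive post-memory iterations; otherwise it runs to $W$ and the result
is flagged `converged = FALSE` rather than raising.  Traces (parameters,
$\delta_k$, acceptance rates, pool size, objective) are always kept and can
be exported with `write_traces_csv()` so convergence can also be judged
graphically.

## The check-loss solver

`weighted_check_regression()` minimizes
$\sum_i w_i \rho_\tau(y_i - x_i'\beta)$ through the linear-programming dual
$\max\{y'a : X'a = (1-\tau)X'\mathbf 1,\ a \in [0,1]^N\}$, solved by a
primal–dual interior point method with Mehrotra's predictor–corrector
(the classical Frisch–Newton approach to quantile regression).  Weights
fold into the design and response since $\rho_\tau(wu) = w\rho_\tau(u)$.
Two numerical notes:

* Quantile-regression optima can be non-unique (any point on an optimal
  face of the polytope).  Solutions are therefore compared through the
  attained objective value, never through coefficient identity; the test
  suite checks the objective against exhaustive basic-solution enumeration
  on small problems and against an independent implementation on larger
  ones.
* Near convergence the Newton normal matrix becomes ill-conditioned; the
  solver retries with a tiny ridge rather than accepting an approximate
  least-squares fallback.

## Post-fit inference

**Marginal log-likelihood.**  The random effects are integrated out by
importance sampling with proposal $N(\hat b_i, \hat\Psi)$ centered at each
subject's smoothed posterior mean; `M` draws per subject (default 1000),
log-sum-exp stabilized, Monte-Carlo standard error reported.  With no
random effects the likelihood is exact and no sampling happens.  Against
1-D quadrature on single-random-effect problems the estimate is accurate to
well under half a percent at the default draw count.

**Standard errors.**  The default (`method = "louis"`) approximates the
observed information by Louis' identity — the posterior-averaged
complete-data information minus the posterior variance of the score —
using fresh Metropolis–Hastings draws at the converged parameters.  Because
the check function has no second derivative, the score is kernel-smoothed
with a Gaussian kernel of bandwidth $h = 0.5\,\hat\sigma N^{-1/5}$
(overridable); as $h \to 0$ with ALD-generated data this recovers the
classical quantile-regression sandwich, and the test suite verifies the
agreement within 15% on a large fixed-effects problem.  A parametric
bootstrap (`method = "bootstrap"`, refits at a reduced iteration budget) is
available as a cross-check.  95% bands use the normal quantile 1.96, as is
conventional for symmetric quantile-fit bands.

**Information criteria.**  `information_criteria()` computes
$\mathrm{AIC} = -2\ell + 2p$, $\mathrm{BIC} = -2\ell + p\log N$ and
$\mathrm{HQC} = -2\ell + 2p\log\log N$.  Two parameter-count conventions
coexist in the literature for mixed models — counting or not counting the
scale parameter alongside the $p$ fixed effects and $r(r+1)/2$ distinct
covariance elements — and published tables are not always internally
consistent about which was used.  Both are exposed
(`count_sigma = TRUE/FALSE`, default `TRUE`); the choice shifts every
criterion by a constant within a fixed model dimension, so rankings of
equal-dimension candidates are unaffected.

**Quantile grids and structure comparison.**  `fit_quantile_grid()` fits a
ladder of quantile levels (default 0.05, 0.25, 0.5, 0.75, 0.85, 0.95) and
returns a tidy table of estimates with 95% bands, suitable for
quantile-profile plots.  Separately fitted quantile curves may cross; the
package diagnoses nothing and repairs nothing in that regard.
`compare_random_structures()` fits a candidate ladder of random structures
at the median with a common seed and ranks by AIC; the default candidates
are a lone time slope, intercept + time, time + square-root time, and
intercept + both slopes.

## The synthetic cohort generator

Because the motivating cohort's data are available only on request, the
package ships a generator (`simulate_qrlmm_data()`) calibrated to the
cohort's published design anchors, so that every pipeline stage is testable
with known truth:

* **Follow-up**: one visit per month from month 0; per-subject length
  beta-binomial on $\{2, \dots, 61\}$ months, centered so the visit-count
  median lands near 29 (the beta concentration, default 8, controls
  overdispersion).  A 235-subject cohort then yields about 7000
  observations.
* **Baseline BMI**: truncated normal on [17.89, 54.89], constants chosen so
  the realized cohort mean sits at 28.93.
* **Log baseline viral load**: truncated normal (median 10.26, sd 2.1) on
  (0.5, 15.52] with a 3% point mass at exactly 0 representing undetectable
  virus.
* **Age**: 18 + a discretized gamma, truncated at 59, median near 25.
* **Therapy initiation**: uniform over the middle half of each subject's
  follow-up (no published distribution exists; configurable through
  `art_window`).
* **Responses**: $y = X\beta + Zb + \varepsilon$ with
  $b_i \sim N_3(0, \Psi)$ and ALD errors at the generating quantile by
  default; Gaussian and $t_3$ families (quantile-shifted so the generating
  quantile stays zero) are available for misspecification studies, where
  only fixed-effect recovery is meaningful since $\sigma$ then loses its
  ALD interpretation.

The default generating truth takes the fixed effects
$(24.6, 0.056, -0.695, 0.082, -0.641, 2.56, 0.029)$ — plausible values for
a median square-root-CD4 model — with $\sigma = 1$ and
$\Psi = \mathrm{diag}(1, 0.04, 0.25)$.  Only the published *marginals*
constrain the generator; the distribution families, the visit process
regularity, and the absence of dropout are package choices.  Passing
recovery tests on these cohorts therefore demonstrates correctness of the
estimation machinery under the stated design, not robustness to
informative missingness, irregular visit schedules, or viral-load
dynamics, none of which are simulated.

## Validation problem sizes

The test suite and the acceptance script validate at sizes chosen to make
Monte-Carlo conclusions stable while keeping full runs at desk scale:
parameter recovery uses 20 replicated cohorts of 100 subjects with 2–10
monthly visits (SAEM at $W = 120$, $c = 0.25$, $m = 10$); the
structure-selection study uses 10 cohorts of 100 subjects with 3–15 visits
and four candidate structures each; oracle-equivalence checks for the
degenerate fixed-effects fit use $N = 500$, $p = 4$ at five quantile
levels.  With these sizes, fixed-effect biases fall within three
Monte-Carlo standard errors, 95% bands cover at 85–100%, and the
generating random structure wins the AIC ranking in at least 8 of 10
replicates.

The selection study's generating covariance deserves a note.  Over a
monthly grid, $1$, $t$ and $\sqrt t$ are nearly collinear — the
unexplained part of $\sqrt t$ after projecting on $\{1, t\}$ has
root-mean-square about 0.3 on a 15-month window and the constant is
similarly well approximated within the span of $\{t, \sqrt t\}$ on long
windows — so a random-effects covariance like $\mathrm{diag}(1, 0.04,
0.25)$ against unit error scale leaves the competing structures almost
likelihood-equivalent and no criterion can (or should) separate them.
The selection study therefore generates with standard deviations
$(1, 0.2, 1)$ for the three effects against error scale $0.5$ on
3–15-month panels, a design where every omitted component costs a
detectable amount of marginal likelihood.  A selection-consistency
experiment is informative only in such a regime; the near-degenerate
regime is a statement about the design, not about the criterion.

## Known limitations

* With short panels (say $n_i \le 10$) and three correlated random-effect
  columns ($1$, $t$, $\sqrt t$ are nearly collinear over short windows),
  $\Psi$ is weakly identified: its elements recover noisily even when the
  fixed effects recover well.  This is a property of the design, not the
  optimizer.
* SAEM estimates carry Monte-Carlo wobble of the order of the smoothing
  window; increase `W` (and hence the number of averaged batches) for
  tighter final averages.
* The draw pool grows linearly in post-memory iterations; for very large
  cohorts combined with very large `W`, memory and M-step cost grow
  accordingly.  The interior-point kernel's shared-design structure keeps
  the constant small, but extreme settings should lower `m` or `W`.
* Extreme quantile levels ($\tau$ outside [0.05, 0.95]) make the ALD
  likelihood nearly degenerate on moderate samples; the fitter warns and
  `tau` is clamped to [0.01, 0.99].
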