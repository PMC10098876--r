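---
title: "Selection-adjusted estimation in seamless phase II/III survival trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection-adjusted estimation in seamless phase II/III survival trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seamtte)
```

## The problem

A seamless phase II/III ("drop-the-loser") trial compares $K$ experimental
arms with a common control. At an interim analysis the stage-1 data are used
to select the promising arm(s); stage-2 patients are then randomized only to
the control and the selected arms, and the confirmatory analysis pools both
stages. Because the same stage-1 data drive both selection and estimation,
the naive combined-data log hazard ratio $\hat\theta_j$ for a selected arm is
biased — typically it exaggerates the benefit of the arm that happened to
look best.

With time-to-event endpoints two features make the normal-outcome theory
non-trivial to carry over:

1. stage-1 log hazard ratio estimates for different arms are **correlated**,
   because every comparison shares the control arm, and
2. stage-1 patients without events are **followed further in stage 2**, which
   couples the two stages unless follow-up is truncated by a prefixed rule.

`seamtte` implements the stage-wise machinery, a family of interim selection
rules, and five point estimators for the selected arms: the naive estimate,
an approximate uniformly minimum variance conditional unbiased estimator
(UMVCUE), single- and multiple-iteration bias-subtracted estimators, and a
two-stage empirical-Bayes shrinkage estimator.

## Stage-wise model

For arm $j$, let $S_{1,j}$ and $V_{1,j}$ be the logrank score statistic and
Fisher information at the interim; asymptotically
$S_{1,j} \sim N(\theta_j V_{1,j},\, V_{1,j})$, so
$\hat\theta_{1,j} = S_{1,j}/V_{1,j} \sim N(\theta_j, \sigma^2_{1,j})$ with
$\sigma^2_{1,j} = 1/V_{1,j}$. The covariance of two stage-1 estimates is

$$q_{ij} = \sigma^2_{1,i}\,\sigma^2_{1,j} \sum_d p_{d,i}\, p_{d,j},\qquad
p_{d,i} = \frac{r_{d,i}}{r_{d,c}+r_{d,i}}$$

summed over shared event times, with $p_{d,i}=0$ when the event occurred in
the *other* experimental arm — so in effect only control-arm events
contribute. In a balanced trial this correlation is close to $1/2$, and
`stage1_covariance()` computes it from the risk sets. Alternatively
(`route = "cox"`, the default, and the recommendation when hazard ratios far
from 1 are plausible) the stage-1 estimates and their covariance come from a
single Cox model with $K$ treatment indicators, and the combined estimate
$\hat\theta_j$, $V_j$ from a pairwise Cox model on the control and arm $j$.

The stage-2 **independent increment** is obtained on the score scale:
$\hat\theta_{2,j} = (S_j - S_{1,j})/(V_j - V_{1,j})$ with variance
$\sigma^2_{2,j} = 1/(V_j - V_{1,j})$; the naive estimate is recovered exactly
as the inverse-variance-weighted combination
$\hat\theta_j = (\sigma^2_{2,j}\hat\theta_{1,j} +
\sigma^2_{1,j}\hat\theta_{2,j})/(\sigma^2_{1,j}+\sigma^2_{2,j})$
(`increment_decompose()` / `combine_increments()` are exact inverses).
Approximate independence of the increment rests on *prefixed* follow-up
rules: the interim and stage-2 triggers, and the calendar extension for
which stage-1 patients without events are followed in stage 2, must all be
set in advance.

## Selection rules and the selection event

Six rules are supported (`selection_rule()`): keep **all** arms with log HR
$\le b$ or with one-sided pairwise p-value $\le a$, keep the **best** arm by
log HR or by p-value, each optionally subject to the futility threshold.
P-values act through $z_j = \hat\theta_{1,j}\sqrt{V_{1,j}}$, so a p-value
threshold $a$ is the log-HR bound $\Phi^{-1}(a)/\sqrt{V_{1,j}}$, and
competitor effects are rescaled by $\sqrt{V_{1,l}/V_{1,j}}$ when compared on
arm $j$'s scale.

Every selection event (including the futility stop) is a rectangle in
linearly transformed coordinates $\hat\delta_1 = A\hat\theta_1$
(`selection_region()`). Selection probabilities and the truncated first
moments $E[\hat\theta_{1,j}\,1_S]$ are then multivariate-normal rectangle
computations (`mvn_rect_prob()`, `mvn_rect_moments()`,
`selection_moments()`). First moments use the boundary decomposition
$E[X 1_R] = \mu P(R) + \Sigma c$, where $c_k$ collects the marginal boundary
densities times conditional $(m-1)$-dimensional rectangle probabilities.

## The estimators

Writing $t_j = V_{1,j}/V_j$, the bias of the naive estimator for a selected
arm is $t_j\{E[\hat\theta_{1,j}1_S]/P(S) - \theta_j\}$; for an unselected
arm (whose naive estimate is its stage-1 value) the factor $t_j$ is absent.

* **SI** subtracts the bias evaluated at the naive vector itself.
* **MI** solves $\tilde\theta = \hat\theta - b(\tilde\theta)$ by functional
  iteration and subtracts $b(\tilde\theta)$. Defaults: sup-norm tolerance
  $10^{-6}$, at most 100 iterations, divergence declared after 10
  consecutive step-doublings; non-convergence is reported as a flag (with
  the last iterate), never as an error, so that a prespecified fallback —
  typically the UMVCUE — can be used.
* **Shrinkage** pulls the stage-1 vector towards the pooled stage-1
  estimate $\hat\theta_{1,\mathrm{all}}$ (control versus all experimental
  arms combined) through the posterior-mean matrix
  $C = I - \Sigma_{\hat\theta_1}(\nu^2 I + \Sigma_{\hat\theta_1})^{-1}$, and
  combines with the unbiased increment:
  $w\,\hat\theta^{(1)}_{j,\mathrm{SH}} + (1-w)\hat\theta_{2,j}$. The prior
  variance $\nu^2$ is estimated by a precision-weighted method-of-moments
  fixed point truncated at zero (`estimate_nu2()`); $\nu^2 = 0$ means
  complete shrinkage to the pooled value. The weight defaults to 0.5, or to
  the planned-events ratio $E_1(|S|+1)/\{E_1(|S|+1)+E_2(K+1)\}$ when event
  counts are supplied.
* **UMVCUE**: the stage-2 increment is unbiased (no selection acts on it),
  so Rao-Blackwellizing it against a complete sufficient statistic yields a
  conditionally unbiased estimator. Given the sufficient statistic
  $\hat\theta^*_i = \hat\theta_{1,i} + (q_{ji}/\sigma^2_{2,j})
  \hat\theta_{2,j}$, the conditional law of $\hat\theta_{2,j}$ is a normal
  truncated to $(B_L, B_U)$, and

  $$\hat\theta_{j,\mathrm{UMV}} = \hat\theta_j - \eta_j
  \frac{\phi(u)-\phi(l)}{\Phi(u)-\Phi(l)},\qquad
  \eta_j = \frac{\sigma^2_{2,j}}{\sqrt{\sigma^2_{1,j}+\sigma^2_{2,j}}},$$

  with $u, l$ the standardized bounds. One-sided truncations are evaluated
  on the log scale (Mills ratios), so the correction is stable far into the
  tails.

### Truncation bounds: a design choice

Each selection constraint is linear in $\hat\theta_{2,j}$ once the
sufficient statistic is held fixed, with slope governed by
$\sigma^2_{1,j} - q_{jl}$ (log-HR comparisons) or
$\sigma_{1,j}\sigma_{1,l} - q_{jl}$ (p-value comparisons). A published
closed form keeps only the single binding constraint (the one attaining the
conditional bound $W_j$). `umvcue_bounds()` instead intersects the bounds
implied by **all** active constraints — the arm's own efficacy/futility
threshold and every competitor comparison. The two coincide whenever a
single constraint binds (in particular for threshold-only rules and for
pure pick-the-winner selection), but for combined best-plus-futility rules
with correlated stage-1 estimates the single-constraint form leaves a
residual conditional bias of order 0.01 on the log-HR scale, which the
intersection removes; we validated this against a normal-theory
Monte-Carlo oracle (conditional bias within 3 simulation standard errors of
zero for all six rules, $\ge 10^5$ selected replicates) and adopted the
exact intersection as the package's behaviour. A constraint whose slope is
exactly zero does not involve $\hat\theta_{2,j}$ and imposes no bound.

For the "all"-type threshold rules the estimator conditions on the event
*arm $j$ continues* (its own threshold only), not on the identity of the
full selected set — this is what makes the closed form exact there, and it
matches the published worked-example values.

## Numerical choices

* Rectangle probabilities: closed form in one dimension; Miwa's
  deterministic lattice quadrature (512 grid points, 128 in dimension 4) in
  dimensions 2–4; randomized quasi-Monte-Carlo (absolute tolerance
  $10^{-6}$, configurable) under a fixed, restored RNG state above that or
  for degenerate covariances. All routes are deterministic across calls.
* Selection probabilities below $10^{-12}$ raise an error (the working mean
  makes the conditioning event numerically impossible), as do two-sided
  $\Phi$-differences below the same floor.
* Ties: Breslow convention in all partial-likelihood fits; tied event times
  in the covariance formula are processed as simultaneous events with risk
  sets fixed at the tie time. Exact ties between arms in best-type rules
  select the lowest index (a measure-zero event, fixed for
  reproducibility).
* Cox fits flag monotone likelihoods (an arm with no events) as explicit
  errors rather than returning divergent coefficients.

## The trial simulator

`trial_design()` + `simulate_trial()` / `replicate_trials()` generate
two-stage trials under proportional Weibull hazards
($h_0(t)=\lambda\gamma t^{\gamma-1}$, $h_j = e^{\theta_j}h_0$): uniform
recruitment at a fixed rate with blocked 1:1:…:1 allocation, interim frozen
at the calendar instant of a prefixed total death count, stage-2 allocation
restricted to control plus the selected arms, stage-2 follow-up stopped at a
prefixed stage-2 death count, and carry-over follow-up of stage-1 patients
censored at a prefixed calendar extension.

The default design is the reference operating-characteristics study: $K=4$,
$\gamma = 0.5$, control median 365 days (so
$\lambda_0 = \ln 2/365^{\gamma}$ — the scale is derived from the stated
median, which is the design intent), one recruit/day, interim at 717
deaths, 316 stage-2 deaths, one-year carry-over, select-the-best rule with
futility boundary 0. The interim and stage-2 event counts are taken as
given design constants; 632 events is the Schoenfeld requirement
(`required_events()`) for 80% power at a hazard ratio of 0.8. Under this
design the continuation probability is 0.80 (for exchangeable stage-1
estimates with correlation 1/2, the probability that all four exceed zero
is exactly $1/(K+1)$) — a useful closed-form cross-check that the survival
layer reproduces.

Conditional bias and RMSE are computed per arm over the replicates in which
that arm was selected; replicates where the MI fixed point fails to
converge are excluded from the MI metrics and counted. Replicates use one
RNG substream per trial drawn from the master seed.

`normal_theory_replicates()` is the fast oracle mode: it draws the
stage-wise estimates directly from the asymptotic joint normal model,
skipping survival simulation entirely. It isolates the estimators'
conditional properties from survival-layer approximations and is how the
UMVCUE's conditional unbiasedness is verified.

### What the generator does and does not emulate

The generator reproduces the features the estimators are sensitive to:
shared-control correlation, event-count triggers on the calendar scale,
selection-then-continuation, and the prefixed carry-over rule. It does not
emulate non-proportional hazards, informative censoring or dropout,
covariates, staggered site activation, or switching of stage-2 patients
away from dropped arms. Passing tests therefore certify the estimators
under (approximately) proportional hazards with administrative censoring —
the regime in which their derivation is valid — not robustness to
violations of it.

## Problem sizes used in the test suite

The packaged checks run the worked example exactly; the
operating-characteristics checks use 2,000–2,500 replicates (the reference
study used 100,000), which gives Monte-Carlo standard errors of about 0.008
on selection probabilities and 0.002 on conditional biases — tight enough
to confirm the reference values at 3 standard errors while keeping a
laptop-scale run. Conditional-unbiasedness checks of the UMVCUE use the
normal-theory mode with at least $10^5$ selected replicates per rule.

## Known limitations

* The UMVCUE is *approximately* unbiased in the survival setting: the
  independent-increment structure is itself an approximation when stage-1
  patients are followed further in stage 2.
* Estimation via the logrank score route degrades for hazard ratios below
  about 0.4; the Cox route is the default and the recommendation.
* Confidence intervals with selection-adjusted coverage are out of scope.
* The rule family is closed over the six rules above; rules whose lower
  bound $L_j$ can be finite are not implemented.

## A worked example

```{r}
fit <- run_worked_example()
fit
```

The UMVCUE and bias-subtracted estimates pull the naive log hazard ratios
towards zero (the selection made them look too good); the shrinkage
estimates move the two arms towards each other and towards the pooled
stage-1 effect.
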