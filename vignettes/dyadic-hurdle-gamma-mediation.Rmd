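---
title: "Dyadic hurdle-gamma mediation models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dyadic hurdle-gamma mediation models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

After a collective trauma such as a flood, families cope both individually
and together. Two causal orderings are plausible for the interplay of
posttraumatic stress symptoms (PTSS), coping self-efficacy (CSE, the
perceived ability to handle recovery demands), and communal coping (the
appraisal that problems are shared and addressed jointly):

* **Disaster-distress direction**: PTSS erodes CSE, and the loss of CSE in
  turn suppresses communal coping (PTSS &rarr; lack of CSE &rarr; communal
  coping).
* **Communal-coping direction**: communal coping builds CSE, which in turn
  lowers PTSS (communal coping &rarr; lack of CSE &rarr; PTSS).

`dyadhg` fits both topologies as Bayesian dyadic multilevel path models over
parent--youth pairs, quantifies the indirect (mediation) effect through lack
of CSE per family member, and compares the two directions with a
bridge-sampled Bayes factor.

## Outcome family and likelihood

PTSS scores are positively skewed; CSE and communal coping are negatively
skewed with ceiling effects. Reverse coding (`scale_max - score`, so the
ceiling maps to exactly 0) turns the latter two into positively skewed
variables with a genuine point mass at zero. Every analysis variable is then
modeled as **hurdle gamma**: a point mass `hu` at 0 and, with probability
`1 - hu`, a gamma law with shape $\alpha$ and mean $\mu = \exp(\eta)$ (rate
$\alpha/\mu$), i.e.

$$p(y) = \begin{cases} hu & y = 0\\
(1-hu)\,\mathrm{Gamma}(y;\, \alpha,\, \alpha e^{-\eta}) & y > 0.\end{cases}$$

Each member $m \in \{\text{parent}, \text{youth}\}$ contributes two
regressions:

$$\eta^{med}_{dm} = \beta^{med}_{0m} + (a_m + u_{dm,a})\,z(x_{dm}) +
u_{dm,0},$$
$$\eta^{out}_{dm} = \beta^{out}_{0m} + (c_m + u_{dm,c})\,z(x_{dm}) +
(b_m + u_{dm,b})\,z(med_{dm}) + u_{dm,0'},$$

where $x$ is the topology's exogenous variable, $med$ is lack of CSE, and
$z(\cdot)$ denotes within-sample z-scoring of covariates (outcomes stay on
their raw hurdle-gamma scale). Standardizing covariates but not outcomes
keeps coefficients on the scale on which the informative priors were
elicited. The indirect effect per member is the per-draw product $a_m b_m$;
its posterior is summarized by exceedance curves
$P(a_m b_m > c)$ and the youth-minus-parent contrast with the one-sided
evidence ratio $p/(1-p)$.

The per-dyad random vector $u_d \in \mathbb{R}^{10}$ (intercepts plus all
independent-variable slopes across the four submodels and both members) is
drawn from $N(0, D\,\Omega\,D)$ with $D = \mathrm{diag}(\sigma_1, \ldots,
\sigma_{10})$ and a full correlation matrix $\Omega$. A single joint block
across members is what makes the cross-pair correlations (e.g. parent vs
youth communal-coping intercepts) estimable. We use the non-centered
parameterization $u_d = D L z_d$, $z_d \sim N(0, I)$, with $L$ the Cholesky
factor of $\Omega$ -- a contract for sampler efficiency, not a substantive
choice.

The hurdle probability is an intercept-only constant per submodel (no
published hurdle regressions exist to motivate more structure), with a
student-t(3, 0, 1) prior on its logit.

## Priors

The informative profile places `normal(0.36, 0.06)` on the PTSS--lack-of-CSE
path (a meta-analytic weighted correlation between self-efficacy and symptom
severity) and `normal(0.21, 0.1)` on the lack-of-CSE--communal-coping path
(mean correlation across prior studies), identically for parent and youth;
everything else -- direct paths, intercepts, random-effect SDs (half-t), and
hurdle logits -- gets the weakly informative `student_t(3, 0, 1)`, and gamma
shapes get `gamma(1, 1)`. The weak profile replaces the two normals with
`student_t(3, 0, 1)` as a sensitivity check. The random-effect correlation
matrix always carries an LKJ(1) (uniform) prior; its normalizing constant is
omitted from reported log marginal likelihoods, which is exact for Bayes
factors between models sharing the 10-dimensional block (both topologies and
both prior profiles do).

## Sampling and diagnostics

No NUTS implementation is available to this package as a dependency, so it
carries its own: multinomial NUTS with dual-averaging step-size adaptation
(target acceptance 0.9 -- conservative for hierarchical geometry), a
windowed diagonal metric, maximum tree depth 10, and divergence flagging at
an energy error of 1000. Gradients of the joint log density (including the
correlation-Cholesky transform) are hand-derived in C++ and verified against
numerical differentiation in the test suite. Initialization is at zero on
the unconstrained scale -- shapes and SDs start at 1, hurdle probabilities
at 0.5 -- matching the published choice of zero initial values read on the
unconstrained scale.

Two profiles are provided. The `paper` profile reproduces the published run
(32 chains x 7,500 iterations, 3,750 warmup, thinning 4; 30,000 retained
draws). The `desk` profile -- 4 chains x 1,500 iterations, 500 warmup, no
thinning -- is the default: at 452 dyads one fit takes on the order of a
minute and yields roughly 4,000 retained draws, ample for posterior means
and 95% intervals. Thinning exists in the paper profile for storage parity
with the original run; the desk profile drops it since the draws are kept in
memory.

Convergence gates follow the published criteria: rank-normalized split
R-hat at most 1.01, bulk ESS above 100 times the number of chains, and tail
ESS above 10% of the total post-warmup draws, all computed per parameter and
reported by `convergence_report()`. Zero-variance chains are flagged rather
than fatal.

## Model comparison

Log marginal likelihoods are estimated by iterative optimal bridge sampling
on the unconstrained scale: half the posterior draws moment-match a
multivariate-normal proposal, the other half enter the bridge identity with
an equal number of proposal draws, iterating to relative tolerance 1e-8
(with Aitken acceleration for the slow oscillatory regime) within 1,000
updates. When fewer fitting draws than parameters are available -- the
usual case for the full model, whose dimension includes every dyad's
innovations -- the proposal covariance is moment-matched on the diagonal
and the reported Monte-Carlo error grows accordingly; for the full dyadic
models the Bayes factor's *direction* (threshold 3) is the meaningful
output, not its magnitude. The estimator is validated against the
closed-form conjugate normal evidence in the tests. Decisions: BF > 3
favors the first model, BF < 1/3 the second, anything between is reported
as inconclusive.

## Preprocessing

The pipeline order is fixed and logged: score scales (means for the 1--7
communal-coping and CSE scales, prorated sums for the 0--4 PTSS scales) ->
exclude dyads in which either member answered none of the three measures ->
random-forest imputation -> reverse coding -> z-scoring of covariates.
Imputation is chained regression forests over the dyad-wide block of all
six analysis variables (both members jointly, so each member's data inform
the other's), iterated until the relative change in imputed values falls
below 1e-4 or 10 sweeps. Whether the original analysis imputed before or
after reverse coding is not stated; imputing first is this package's fixed
choice, and because the reversal is affine the choice only matters through
the forests' nonlinearity. Partial responses are prorated rather than
dropped -- a decision, as the source is silent.

## The synthetic-data generator

`generate_dyads()` draws from exactly the generative form the models assume
-- hurdle-gamma outcomes, log link, one jointly correlated 10-vector of
dyad random effects -- because no raw data are deposited and the original
papers only fit models without stating a data-generating process; the
models' own form is the minimal structure that makes recovery tests
meaningful. Defaults are the study conditions: 452 dyads, fixed effects and
intercepts at the published posterior means, exogenous marginals matched to
the published descriptives (PTSS item-mean 1.38; reverse-coded communal
coping 1.42), gamma shapes 2 and hurdle probabilities 0.1 (unreported in
the source; chosen once as realistic for the published zero spikes and
dispersion), random-effect SDs 0.2 with an identity correlation default,
and 2.3% MCAR missingness. `days_since_event` is generated as independent
noise (published correlations with every study variable are near zero) and
never enters the models.

What the generator does **not** emulate: item-level response processes
(only a deliberately simple equal-loading simulator exists for reliability
tests), missingness that depends on the data (the study reports no MNAR
analysis), covariates such as exposure or SES, and any misspecification --
so passing recovery tests demonstrates correctness of the machinery under
the model's own assumptions, not robustness of the model on real data.

## Recovery as the acceptance surface, and a known limitation

`recovery_study()` generates at the published point estimates and refits
with the desk profile. Recovery fits use the weakly informative profile by
design: a recovery simulation should measure what the data identify, and
the informative `normal(0.36, 0.06)` prior would deliberately pull the PTSS
coefficients (true values near 0.25) toward 0.36. Fixed effects are
recovered within about +/-0.05 at 452 dyads.

Intercept--slope random-effect correlations are a different matter. With
one observation per dyad per submodel, the correlation between a dyad's
intercept and its own slope is informed only through how the variance of
the combined effect $u_0 + u_1 z(x)$ changes with $x$ -- a second-order
signal. At 452 dyads that information is thin, and the LKJ(1) prior over a
10 x 10 correlation matrix (whose single-entry marginal concentrates around
0 with SD about 0.29) dominates: generating with a true correlation of
-0.89 and SDs of 0.3 yields posterior means near -0.1. The machinery is
consistent -- at 3,000 dyads the same code recovers -0.75 with a credible
interval covering the truth -- but the study-scale design cannot recover a
strong intercept-slope correlation. By the same token, strongly negative
posterior intercept--slope correlations estimated from real data of this
size are better read as posterior collinearity between weakly separated
intercepts and slopes than as sharp generative structure. The package
reports these entries honestly with their (wide) credible intervals.

## Bayesian correlation tables

`bayesian_correlations()` z-scores the requested variables, fixes
intercepts at 0 and residual scales at 1, and samples the free correlation
matrix under LKJ(1) with 4 chains x 2,000 iterations (1,000 warmup). For
reporting, reverse-coded variables are sign-restored so the table reads on
the original instrument coding.

## Numerical choices and degenerate inputs

* Gamma parameterized by shape and mean (rate $\alpha/\mu$); log link.
* `hu` is constrained to `[0, 1)`; a saturated hurdle is representable in
  the generator but not as a posterior point.
* Zero-row data are legal everywhere and yield prior-only fits; prior
  recovery is a standing test.
* Ties in the member-difference draws use the midpoint convention
  (`P(d > 0) + P(d = 0)/2`), so identical members give probability 0.5 and
  evidence ratio 1.
* Exceedance uses strict inequality; ties have probability zero under
  continuous draws.
* Zero-variance columns, non-PSD correlation inputs, out-of-range item
  responses, and fully missing variables raise immediate, named errors.
* Reproducibility: a seed fixes the generator byte-for-byte and the sampler
  exactly on a given platform/toolchain (the sampler's RNG is a C++
  mt19937_64, so cross-platform bit equality is not promised).

## Problem sizes used in the shipped checks

The test suite exercises full-scale recovery (452 dyads, desk profile) for
both topologies plus the focal correlation, a 20-cycle simulation-based
calibration smoke test at 30 dyads with concentrated priors, and smaller
fits for interface behavior; generator-level laws are checked at 10,000 to
50,000 dyads where Monte-Carlo error bounds demand it. These sizes are the
package's own validation choices: large enough that the stated tolerances
are meaningful, small enough to run routinely.
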