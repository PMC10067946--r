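---
title: "A hierarchical Bayesian model for longitudinal multiple-flow FeNO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical Bayesian model for longitudinal multiple-flow FeNO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `fit_l_u_hb()`, the
assumptions it makes, how the synthetic-data generator mirrors it, the
numerical design of the sampler, and the model's known limitations. Code
chunks are illustrative and not evaluated when building the vignette; the
quantitative statements below are the ones computed by the package's test
suite and by `scripts/acceptance.R`.

## The two-compartment model

A maneuver at expiratory flow $V$ (ml/s) produces a FeNO reading whose
steady-state two-compartment prediction is

$$\mathrm{FeNO}(V) = C_{aw} + (C_A - C_{aw})\, e^{-D_{aw}/V},$$

with alveolar concentration $C_A$ (ppb), airway tissue concentration
$C_{aw}$ (ppb) and airway wall diffusing capacity $D_{aw}$
(pL·s⁻¹·ppb⁻¹). The curve decreases monotonically from $C_{aw}$ (slow
flows, airway-dominated) toward $C_A$ (fast flows); `feno_2cm()` implements
it and the unit tests pin it to hand-computed values and its limiting
behaviour. Because $C_{aw}$ and $D_{aw}$ are positive and right-skewed the
model works with $\log C_{aw}$ and $\log D_{aw}$; the session parameter
vector is $\theta = (C_A, \log C_{aw}, \log D_{aw})$.

## The three-level hierarchy

For participant $i$, visit $j$, maneuver $k$ at flow $V_{ijk}$:

* **Maneuver level.** $\log \mathrm{FeNO}_{ijk} \sim
  N(\log f(\theta_{ij}, V_{ijk}),\ \sigma_\varepsilon^2)$ — a
  transform-both-sides log-normal error, matching the multiplicative noise
  of NO analysers.
* **Visit level.** $\theta_{ij} = \beta_0 + \beta_1 x_{ij} + \alpha_i +
  \alpha_{ij}$ with within-participant visit deviations $\alpha_{ij} \sim
  N_3(0, \mathrm{diag}(\sigma_{v1}^2, \sigma_{v2}^2, \sigma_{v3}^2))$,
  truncated so that the $C_A$ component of $\theta_{ij}$ is non-negative.
  $x_{ij}$ is a session-level covariate and $\beta_1$ — the association of
  each NO parameter with $x$ — is the inferential target.
* **Participant level.** $\alpha_i \sim N_3(0, \Sigma_\tau)$ with a full
  (unstructured) $3\times 3$ covariance: participants high in one NO
  parameter tend to be high or low in the others.

Priors are deliberately vague: $\beta \sim N(0, 10^3)$ componentwise,
$\Sigma_\tau \sim \mathrm{Inv\text{-}Wishart}(\nu = 4,\ 0.001\, I_3)$, and
$\sigma_{vc}^2, \sigma_\varepsilon^2 \sim \mathrm{Inv\text{-}Gamma}(0.001,
0.001)$ (`prior_spec()`).

Key assumptions: maneuver errors are independent log-normal given the
session parameters; the covariate acts linearly and additively on all three
components; visit deviations are uncorrelated across components (all
cross-component correlation lives at the participant level); sessions share
one $\sigma_\varepsilon$.

## The synthetic-data generator

`simulate_feno_dataset()` draws from exactly this hierarchy, so the
generator is the model's own data-generating process: participant effects
from $N_3(0, \Sigma_\tau)$, visit effects from the diagonal normal, a
standard-normal session covariate, and log-normal maneuver noise around the
two-compartment curve. Sessions whose $C_A$ falls below zero are redrawn
(rejection sampling at the participant level), and the attempted/rejected
counts are returned so tests can check the rejection rate against its
closed-form approximation. Reference population values
(`default_population_params()`): $\beta_0 = (1.5, 3.5, 2.5)$,
$\tau = (0.45, 0.65, 0.55)$ with correlations $(0.66, -0.38, -0.35)$,
$\sigma_v = (0.5, 0.4, 0.33)$. The maneuver noise default is
$\sigma_\varepsilon = 0.10$ on log FeNO, a deliberate design choice
representing realistic analyser repeatability; the flow schedule default is
two maneuvers at each of 30/50/100/300 ml/s, with a 9-maneuver
50/100/300-based alternative (`flow_schedule("chs")`). The generator's
scope is purely this design: balanced visits, one Gaussian session
covariate, no missingness mechanism beyond estimator failure downstream.
`scenario_beta()` encodes the four covariate-effect patterns used in the
simulation studies (effect on all three parameters, or on exactly one).

## Sampler design

`fit_l_u_hb()` runs a compiled (RcppArmadillo) Metropolis-within-Gibbs
sampler; all randomness flows through R's RNG so fits are exactly
reproducible from `mcmc_config(seed = )`. One sweep updates:

1. **Session parameters $\theta_{ij}$** — joint 3-dimensional
   random-walk MH per session, with proposal covariance from a Gauss–Newton
   approximation $(J^\top J/\sigma_\varepsilon^2 +
   \mathrm{diag}(1/\sigma_v^2))^{-1}$ frozen mid-warmup, and an adaptive
   scalar step size. Per-session residual sums of squares are cached so a
   sweep touches each maneuver once.
2. **Translation moves** — the posterior induced by the vague
   inverse-Wishart prior is bimodal at small $n$ (see below), and plain
   Gibbs mixes poorly across the implied reparametrisations. Extra moves
   translate $\beta_0$ (componentwise and jointly) together with *all*
   $\theta_{ij}$, leaving every hierarchy residual invariant so only the
   likelihood changes; an analogous move shifts $\beta_1$ together with
   $x_{ij}$-proportional shifts of the $\theta_{ij}$. Both adapt their
   proposal scales and covariances during warmup.
3. **Covariance block** — a partially collapsed 9-dimensional adaptive MH
   update of (the Cholesky factor of $\Sigma_\tau$, $\log \sigma_v^2$)
   with the participant effects $\alpha_i$ integrated out analytically;
   every tenth proposal uses a 3× scale to jump between posterior modes.
4. **Regression coefficients $\beta$** — an exact generalised-least-squares
   draw from the marginal (with $\alpha$ collapsed) Gaussian full
   conditional.
5. **Participant effects $\alpha_i$** — exact multivariate-normal full
   conditional (which also validates the partial collapsing in 3–4).
6. **$\sigma_\varepsilon^2$** — conjugate inverse-gamma draw from the
   cached residuals.

Correctness was established three independent ways: the collapsed marginal
log-posterior matches a direct `mvtnorm` computation; the test suite fits
the identical model in `rjags` (used *only* as a cross-check oracle) and
compares posterior means; and recovery tests verify coefficient posterior
means land within Monte-Carlo error of the generating values.

### Bimodality and the convergence diagnostic

The $\mathrm{IW}(4, 0.001 I)$ prior concentrates $\tau$ near zero a priori
and conditionally favours $|\rho| \to 1$. At moderate sample sizes
(e.g. 100 participants) the joint posterior genuinely carries a second,
near-singular mode alongside the truth-like one; this is posterior
geometry, not a sampler defect (the same behaviour appears in the
independent `rjags` fit and disappears at larger $n$). The mode-jumping
and translation moves exist to traverse it. Because variance-component
draws wander between modes, the fit-level `converged` flag gates split-
R-hat on the *reported coefficients* only ($\beta_1$ when a covariate is
present, $\beta_0$ otherwise); the full R-hat table for every monitored
parameter remains in `fit$summary`. In the simulation harness,
`converged` uniformly means "the method produced estimates" — completed
MCMC fits are never excluded on a noisy diagnostic, which would select
replicates by their estimates and bias the aggregated metrics.

## Estimators for comparison

* `session_table(d, "nls")` — per-session transform-both-sides nonlinear
  least squares with multi-start optimisation and physiological sanity
  bounds; failures are recorded as data.
* `session_table(d, "hma")` — the Högman–Meriläinen third-order
  three-flow algorithm, solved exactly at 30/100/300 ml/s medians.
* `fit_l_ts_nlme_stage1()` / `fit_l_u_nlme()` — Laplace-approximation
  nonlinear mixed models (via `nlme`), covariate-free and unified.
* `fit_l_ts_hb_stage1()` — the covariate-free Bayesian hierarchy, whose
  posterior-mean session estimates feed `fit_stage2_lmm()`, a
  random-intercept linear mixed model (`lme4`, Wald intervals, OLS
  fallback at the boundary).

## Numerical and design choices

* Transform-both-sides on the log scale stabilises the multiplicative
  maneuver noise and makes $\sigma_\varepsilon$ interpretable as a
  coefficient of variation (~10%).
* The $C_A \ge 0$ constraint is enforced in the generator by rejection and
  in the sampler by proposal rejection — both exact truncations of the
  same distribution.
* Chains default to `mcmc_config()`'s two chains; the simulation harness
  uses one 1000+2000 chain per fit to keep a 60-fit study inside a
  15-minute budget, and the acceptance study uses 400 participants so that
  the power targets are attainable at effect size 0.1.
* Per-replicate seeds derive deterministically from a master seed
  (`fenolong:::replicate_seed`), so any replicate can be reproduced in
  isolation; `run_simulation_study()` can checkpoint each replicate to CSV.

## Limitations

* Visit-level deviations are assumed independent across components;
  cross-component correlation is modelled only between participants.
* A single session covariate with a linear effect; no time trends,
  measurement error in $x$, or unbalanced designs.
* The vague inverse-Wishart prior is kept for comparability, but it is
  informative near singularity at small $n$; analyses at 100 participants
  should expect wide, occasionally bimodal variance-component posteriors
  (coefficient inference is robust to this in the packaged studies).
* The Laplace-approximation unified fit (`fit_l_u_nlme()`) inherits
  `nlme`'s fragility on ill-conditioned datasets and reports
  non-convergence rather than estimates in those cases.
* Session-level estimators need at least four maneuvers at three or more
  distinct flows (NLS) or the designated 30/100/300 levels (HMA).
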