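# fenolong

Longitudinal modelling of multiple-flow exhaled nitric oxide (FeNO).

## Scientific background

FeNO is a biomarker of airway inflammation, conventionally reported at a
single expiratory flow of 50 ml/s. Measuring FeNO at *several* flows in one
session lets the steady-state two-compartment model of NO exchange partition
the signal into three physiologically distinct "NO parameters":

* `C_A` — alveolar NO concentration (ppb),
* `C_aw` — airway tissue NO concentration (ppb, modelled on the log scale),
* `D_aw` — airway wall diffusing capacity (pL·s⁻¹·ppb⁻¹, log scale).

The two-compartment prediction for a maneuver at flow `V` is

```
FeNO(V) = C_aw + (C_A − C_aw) · exp(−D_aw / V)
```

In a longitudinal panel study each participant contributes several visits,
and each visit several maneuvers across a flow schedule. The scientific
question is how the NO parameters relate to a session-level covariate
(e.g. an exposure or anthropometric variable). Two estimation strategies
compete:

* **Two-stage (`L_TS_*`)** — Stage I estimates the NO parameters separately
  per session (nonlinear least squares, the Högman–Meriläinen three-flow
  algorithm, a nonlinear mixed model, or a covariate-free Bayesian fit);
  Stage II regresses those estimates on the covariate with a participant
  random intercept. Simple, but Stage-I estimation error does not carry
  into Stage II, and with realistic maneuver noise single-session fits fail
  often and are strongly correlated across parameters, which biases
  Stage-II associations and invalidates their type-I error.
* **Unified (`L_U_HB`, `L_U_NLME`)** — one three-level nonlinear
  mixed-effects model estimates the NO parameters and their covariate
  associations simultaneously. The Bayesian version (`fit_l_u_hb()`) is the
  package's centrepiece: maneuver-level log-normal errors, session-level
  NO parameters with a covariate term and diagonal visit-to-visit
  covariance, participant-level random effects with an unstructured 3×3
  covariance, a non-negativity constraint on `C_A`, and vague conjugate-style
  priors, fitted by a compiled Metropolis-within-Gibbs sampler.

The package also ships a synthetic-data generator for the full three-level
design and a simulation harness (`run_simulation_study()`) that computes
percent bias, interval length and coverage, power, and type-I error across
methods and covariate-effect scenarios.

## Worked example

Simulate a 100-participant, 3-visit study (8 maneuvers per session at
30/50/100/300 ml/s) in which the covariate shifts every NO parameter by
0.1 per unit, then fit the unified Bayesian model:

```r
library(fenolong)

pop <- default_population_params(beta1 = scenario_beta(1, 0.1))
d   <- simulate_feno_dataset(pop, n_participants = 100, n_visits = 3, seed = 42)

fit <- fit_l_u_hb(d, mcmc = mcmc_config(n_chains = 2, n_warmup = 1000,
                                        n_iter = 2000, seed = 43))
coef_estimates(fit)
#>        target estimate     se    lower upper significant method n_used
#> 1     beta_ca    0.136 0.0391  0.05999 0.212        TRUE L_U_HB    300
#> 2 beta_logcaw    0.071 0.0549 -0.04794 0.173       FALSE L_U_HB    300
#> 3 beta_logdaw    0.119 0.0628  0.00532 0.255        TRUE L_U_HB    300
```

All three true slopes are 0.1; each 95% credible interval above covers its
target. Because `beta_logcaw` and `beta_logdaw` act on the log scale they
transform directly to percent changes — e.g. a log-scale coefficient of
0.158 is a `100·(exp(0.158)−1) ≈ 17%` increase per covariate unit.

Per-session estimation on the same data shows why the unified model earns
its keep at realistic noise (`sigma_eps = 0.10` on log FeNO):

```r
tab <- session_table(d, "nls")
attr(tab, "failure_fraction")
#> [1] 0.2866667        # 29% of single-session NLS fits fail outright
tab[tab$converged, ][1, c("ca", "logcaw", "logdaw")]
#>     ca logcaw logdaw
#> 2 1.55   4.63   2.34  # truth for that session: 1.54, 4.39, 2.56
```

(The Högman–Meriläinen algorithm, `session_table(d, "hma")`, fails on 26%
of these sessions.)

## Simulation study

`run_simulation_study()` replicates the full pipeline — generate, fit,
aggregate — over covariate-effect scenarios (effect on all three parameters,
or on exactly one) with deterministic per-replicate seeds and optional CSV
checkpointing. In the package's acceptance study (400 participants ×
3 visits, effect size 0.1, master seed 2025; reproduced by the test suite)
the unified Bayesian method showed percent bias of −7.4%, −6.5% and +8.1%
for `beta_ca`, `beta_logcaw`, `beta_logdaw` with 95% interval coverage of
1.00, 1.00 and 0.95 over 20 Scenario-1 replicates; power 1.00 for `beta_ca`
(Scenario 2) and 0.80 for `beta_logdaw` (Scenario 4) with null rejection
rates ≤ 0.2 over 10 replicates. The two-stage Bayesian method on the same
datasets attenuated `beta_ca` by −38% and `beta_logdaw` by −62% and
rejected the *null* `beta_logcaw` in 10/10 Scenario-4 replicates (type-I
error 1.00 vs 0.20 in Scenario 2) — the cross-parameter contamination that
motivates the unified model.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "fenolong",
                               load_package = "installed")'
```

The suite includes exact analytic oracles (hand-computed two-compartment
values, grid-search checks of the NLS objective, closed-form
Högman–Meriläinen solutions), an independent cross-check of the Gibbs
sampler against `rjags` on the same model and data, and the scaled
acceptance study above (the acceptance file runs ~60 MCMC fits and takes
about 15 minutes; the other files run in ~3 minutes).

## Reproduction

The headline quantities can be regenerated against the installed package
with any seed:

```sh
Rscript scripts/acceptance.R --seed 2025 --out results.json
```

This writes the analytic percent-change transforms, the single-fit
coefficient recovery table, and the simulation-study metrics (bias,
coverage, power, type-I error for both hierarchical-Bayes methods) to
JSON. Runtime is roughly 12 minutes on one CPU; progress is logged to
stderr.

## Vignette

`vignettes/feno-hierarchical-model.Rmd` documents the model, priors,
sampler design (including the partially collapsed covariance update and
the translation moves that handle a bimodal posterior geometry induced by
the vague inverse-Wishart prior at small sample sizes), the synthetic-data
generator's scope, and known limitations.
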