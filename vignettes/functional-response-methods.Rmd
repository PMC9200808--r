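---
title: "Comparative functional response analysis with frcompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative functional response analysis with frcompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frcompare)
library(dplyr)
```

## The problem

Comparative functional response analysis quantifies how a consumer's
*per-capita* feeding rate changes with resource density, and compares that
relationship across contexts — predator sex, temperature, salinity,
invasion status. The motivating application is a predatory crab feeding on
sessile bivalve prey in factorial laboratory trials: prey are offered at a
range of initial densities, are **not replaced** as they are eaten, and the
number killed per trial is recorded. `frcompare` implements the full
analysis chain such experiments use:

1. a factorial **consumption-rate model** (quasibinomial GLM, Type III
   analysis of deviance, backward elimination, slope contrasts);
2. **functional response type determination** by logistic regression, with
   a LOWESS visual diagnostic;
3. maximum-likelihood fitting of **Rogers' random predator equation** and
   the derived impact metrics (maximum feeding rate $1/h$, functional
   response ratio $a/h$);
4. **nonparametric bootstrap** confidence intervals and curve envelopes;
5. a **stochastic foraging simulator** that generates whole factorial
   experiments with known parameters, used throughout the test suite and
   available for power analysis.

## The random predator model

For a trial of duration $T$ starting with $N_0$ prey, the expected number
killed $N_e$ under a Type II response without prey replacement solves the
implicit equation

$$N_e = N_0\left(1 - e^{a\,(N_e h - T)}\right),$$

where $a$ is the attack (clearance) rate and $h$ the handling time. The
unique root in $[0, N_0]$ has the closed form

$$N_e = N_0 - \frac{W\!\big(a h N_0\, e^{-a (T - h N_0)}\big)}{a h},$$

with $W$ the principal Lambert branch. `rogers_expected_kills()` evaluates
this through `lambert_w_exp()`, a log-domain $W(e^z)$: the W argument's
exponent grows linearly in $a h N_0$ and overflows double precision for
parameter values an optimizer routinely visits, so the package never forms
the argument itself, only its logarithm. Newton iteration on
$g(w) = w + \log w - z$ is monotone and quadratically convergent for
$w > 0$; for $z < -30$ a two-term series is exact to beyond double
precision. The solver is validated against an independent bisection oracle
to $10^{-9}$ relative error.

### Units

Durations are stored in *experimental-period* units: `duration = 1` is one
feeding period, whose wall-clock length (72 h by default) is design
metadata only. Fitted attack rates are per period, handling times in
periods per prey, and the maximum feeding rate $1/h$ in prey per period.
This matches how such experiments are conventionally parameterised — the
magnitudes of $1/h$ are then directly comparable with the densities
offered.

### Likelihood and fitting

`fit_rogers()` maximises a binomial likelihood: each trial's kill count is
$\mathrm{Binomial}(N_0, N_e(N_0, a, h, T)/N_0)$. This is the standard
likelihood for non-replacement designs; it remains well defined under
total prey depletion because expected fractions are clamped to
$[10^{-9}, 1 - 10^{-9}]$. Optimization is over $(\log a, \log h)$ —
positivity by construction — with a Nelder–Mead search from a Hanes-type
linearisation of the disc equation ($T/N_e$ regressed on $1/N_0$; fallback
$(a, h) = (1, 1/\max N_0)$), followed by a BFGS polish at a $10^{-8}$
relative tolerance on the objective. Standard errors come from the inverse
numerical Hessian on the log scale and are delta-method transformed.
Impact metrics ($1/h$, $a/h$) are exact arithmetic on the unrounded
estimates.

## Functional response type

The classification rule is the standard sign/significance scheme on
logistic regressions of proportion killed against density: a significant
**negative first-order term** indicates a Type II response; a significant
positive first-order term followed by a significant negative second-order
term in the quadratic fit indicates Type III. `type_test()` applies the
rule sequentially: the headline first-order term comes from the
**linear** logistic fit, and the quadratic fit is consulted for the
Type III branch (both are reported). This was a genuinely open design
choice — one could instead read the first-order term off the quadratic
model — but the sequential form is what the established functional
response toolchains do, and the quadratic model's strong collinearity
between $N_0$ and $N_0^2$ inflates the first-order standard error enough
to halve Type II detection power at realistic replication. Wald $z$ tests
at $\alpha = 0.05$ are used; complete separation is flagged and yields an
indeterminate call rather than a diverged coefficient.

`lowess_proportions()` provides the accompanying visual diagnostic: a
tricube local-linear LOWESS (span 9/10, zero robustifying iterations by
default) of proportion killed against density, clipped to $[0, 1]$.

## Bootstrap uncertainty

`bootstrap_fit()` resamples trial rows with replacement (same $n$,
unstratified — the common nonparametric functional response bootstrap),
refits per replicate from a warm start at the point estimate, and returns
percentile 2.5/97.5 intervals for the parameters plus a pointwise 95%
envelope of the fitted curve over a density grid (default: integers up to
the maximum observed density). Percentile intervals are computed on the
natural $(a, h)$ scale directly from the draws, so they are equivariant
under the log reparameterisation used in fitting. Replicates whose refit
fails (e.g. a resample with no kills, or a single density) are dropped and
counted, never redrawn — redrawing would make the seed-to-output map
depend on the failure pattern. More than 20% failures attaches a warning.
`envelope_overlap()` compares two groups' envelopes per grid density;
disjoint envelopes across a density range are the standard visual evidence
of a magnitude difference.

The default `n_boot = 2000` follows common practice; the package's own
calibration checks run at reduced sizes (500 and 200 replicates over 100
to 200 simulated experiments) to keep the suite fast, which widens the
Monte-Carlo noise on the coverage estimate but does not bias it.

## The factorial consumption-rate model

`fit_quasibinomial()` models the proportion killed by sex, temperature and
salinity (factors) and prey density (continuous, untransformed — each of
its tests then has a single degree of freedom), with interactions up to
the four-way term. The binomial-logit IRLS is weighted by $N_0$;
the quasibinomial family leaves the coefficients **identical** to the
binomial fit and scales inference by the Pearson dispersion
$\hat\varphi = \chi^2 / \mathrm{df}_\mathrm{resid}$, the package's
overdispersion diagnostic.

Two things deserve loud documentation:

* **Sum-to-zero contrasts are enforced.** Type III tests compare the full
  model with the model lacking one term while retaining all others; under
  treatment coding those comparisons test parameters nobody intends.
  `anova_type3()` removes each term's design-matrix columns, refits, and
  forms $F = (\Delta D / \Delta\mathrm{df}) / \hat\varphi$ on
  $(\Delta\mathrm{df}, \mathrm{df}_\mathrm{resid})$.
* **The classical Type I = Type III equivalence in balanced designs is a
  linear-model result.** In a GLM the IRLS metric varies with the fitted
  cell means, so even perfectly balanced data give exact equality only for
  the highest-order term; lower-order terms agree approximately. The test
  suite asserts exactly that.

`backward_select()` removes one term per step — the highest Type III
p-value at or above $\alpha$ among *removable* terms (those not contained
in a term still present, so marginality is respected and main effects
under retained interactions are immune) — refitting until all removable
terms are significant. Because p-values are recomputed after each
removal, a term that looked ignorable in the full model can become
significant and be retained; this path dependence is inherent to stepwise
schemes and is why the full-model deviance table is reported alongside
the reduced model.

`density_slope_contrast()` replaces the usual post-hoc machinery with an
explicit Wald contrast: the difference between two temperatures, within a
sex, of the logit-scale density slope, averaged over the remaining
factors. The contrast vector is built numerically from the model matrix
(exact, since density enters linearly), and its variance uses the
dispersion-scaled covariance, so the standard error scales with
$\sqrt{\hat\varphi}$.

## The synthetic experiment generator

`simulate_experiment()` fills a factorial design
(`fr_design()`: densities 1–64 in eight steps, five predator replicates
per sex × temperature × salinity × density cell, three predator-free
controls per abiotic cell — 416 units) from a scenario
(`fr_scenario()`). The default parameter map
(`default_fr_params()`) is a strongly sexually dimorphic predator: male
attack rates 1.34–3.13 per period with handling times 0.032–0.080
(lengthening with warming), female attack rates 0.56–0.84 with handling
times 0.156–0.181. Controls draw
$\mathrm{Binomial}(N_0, 0.005)$ background kills — better than 99%
control survival, so the background-mortality check passes without
correction, as in well-run trials. A single RNG stream is seeded once and
per-trial sub-seeds are drawn up front, making every row reproducible and
independent of evaluation order.

Two trial-level generators are available:

* `simulate_trial_binomial()` draws from the exact observation model the
  likelihood assumes — the right choice for calibration studies.
* `simulate_trial_mechanistic()` is an event-driven forager: exponential
  search times at rate $aN$, one prey removed per capture, a fixed
  (degenerate) handling delay — fixed rather than exponential so the
  process's deterministic limit is the disc-equation derivation behind the
  Rogers model. Prey are identical, sessile and do not respond
  behaviourally.

The mechanistic process is a *finite-population* analogue, not the
mean-field equation: its mean sits about 1% above the Rogers solution in
depletion-driven regimes (up to ~5% when handling dominates), a
demographic/discreteness bias that no number of replicates removes. The
test suite asserts agreement at these scales rather than pretending the
two coincide to Monte-Carlo error.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: between-individual predator heterogeneity,
prey size structure and selection, temporal nonstationarity within the
feeding period, predator interference, alternative prey, or overdispersion
beyond binomial noise. Results on real experiments depend on those
features; the generator certifies the *statistical machinery*, not the
biology.

## Numerical choices, degenerate inputs, tie-breaks

* Expected-kill fractions clamped at $\varepsilon = 10^{-9}$; keeps total
  depletion finite in the likelihood.
* All kills zero → no-information error (the attack rate is not
  identifiable); a single density → ill-posed warning carried on the fit.
* Bootstrap refits: warm start, BFGS only, failures dropped
  deterministically.
* Backward elimination tie-break: one term per step, highest p first.
* Trials at $N_0 = 1$ contribute proportions in $\{0, 1\}$ and are
  retained — no exclusion rule.
* LOWESS uses `iter = 0` (plain tricube weights); the span is the
  only smoothing parameter exposed, defaulting to 9/10.
* Factor levels in trial CSVs are matched case-insensitively; controls
  carry no sex.

## Problem sizes used by the test suite

The suite's simulation studies use the design's own scale (40 trials per
treatment group; 320 predator trials per experiment): 50 experiments for
parameter-recovery bias at 1× and 10× replication, 200 experiments at
`n_boot = 500` for bootstrap coverage, 200 simulations for Type II
detection power, and 500 runs each for the type-test and sex-test size
checks. These sizes give binomial standard errors of 1–2 percentage
points on the estimated rates, which is the resolution at which the
calibration claims are asserted.

## Worked example

```{r example, eval = FALSE}
trials <- simulate_experiment(fr_design(), fr_scenario(), seed = 1)
report <- run_analysis(trials, fr_config(n_boot = 500, seed = 1))

report$summary          # per-group type call, a, h, 1/h, FRR, bootstrap CIs
report$deviance_table   # Type III F tests with retained flags
report$slope_contrasts  # temperature-within-sex density slope contrasts

autoplot(report$bootstraps[[1]])   # envelope for the first group
plot_proportions(trials)           # LOWESS diagnostic
```

## Known limitations

* Only the Type II (Rogers) model is fitted; sigmoidal Type III and
  flexible-exponent models are out of scope, as are replacement designs
  and within-trial time series.
* No predator interference or multiple-predator effects; one predator per
  trial is assumed.
* The bootstrap treats trial rows as exchangeable (no stratification by
  density); with very few replicates per density, resamples occasionally
  lose all information and are dropped.
* Stepwise selection inherits the usual caveats of data-driven model
  reduction; the full model's deviance table is always reported so readers
  are not hostage to the path taken.
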