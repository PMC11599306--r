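---
title: "Models and methods behind hostassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hostassay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hostassay)
```

`hostassay` analyses common-garden rearing assays in which insect larvae
from several source populations are reared on a panel of host plants, in
group cultures, with performance scored as survival to pupation, pupal mass
and development time. This vignette is the package's own account of its
models, the choices behind them, and what its simulations can and cannot
show.

## The experimental structure

The reference layout crosses 4 source populations with 9 host-plant
treatments; each population-by-host cell holds 5 rearing cultures of 20
larvae (3600 in total). Larvae descend from per-population pools of
wild-caught females ("broods": 15, 14, 126 and 19 across the four
populations) and are assigned to treatments and cultures at random across
broods, so cultures are mixed-brood and individual brood membership is
unrecorded — a deliberate trade-off in the assay that the package's
design-evaluation module interrogates (see below).

## The three models

Each response gets its own variance-component model on its link scale, with
only an intercept as fixed effect and random intercepts for population,
host, population-by-host and culture:

* **Survival**: binary outcome with a logit link. Each individual carries a
  latent log-odds whose likelihood is Bernoulli and whose prior is normal
  around the linear predictor with a **fixed** residual variance (default
  1). A binary observation cannot identify a residual variance, so fixing
  it sets the scale of the link; all variance components are interpreted
  relative to it.
* **Pupal mass** (mg): Gaussian, with an additional two-level `sex` random
  term. Sex enters only this model because sexing requires a pupa: larvae
  that die cannot be sexed, so a sex term in the survival or
  development-time models would be conditioned on the outcome.
* **Development time** (days): Gaussian, same structure as survival's
  linear predictor.

The Gaussian models are fitted to survivors with a recorded value; rows
with a missing response are dropped (reported by message). Group effects
are not sum-to-zero constrained: hierarchical shrinkage through their
variance identifies them, which matches the prior structure below.

### Priors

The intercept gets Normal(0, 1e8). Every variance component gets a scalar
inverse-Wishart prior with scale `V = 1` and degrees of freedom
`nu = 0.002`, i.e. Inv-Gamma(shape 0.001, rate 0.001) — weakly informative,
and the long-standing default of the variance-component software family
this model class comes from. The Gaussian residual variance takes the same
prior; the binary residual is fixed (default 1). All of this is exposed in
`prior_spec()`.

### Samplers

Both samplers live in compiled code (`src/samplers.cpp`).

* The Gaussian sampler is fully conjugate Gibbs: the intercept and each
  block of group effects are drawn from normal full conditionals; each
  variance from its scaled inverse-chi-square full conditional
  (`Inv-Gamma((nu + k)/2, (nu V + sum u^2)/2)`).
* The binary sampler adds a Metropolis step for the latent log-odds:
  a random-walk proposal whose global scale adapts towards 44% acceptance
  in batches during burn-in only, then freezes (so the post-burn-in chain
  is a valid fixed-kernel MCMC). The intercept starts at the empirical
  log-odds and the latents just above/below it, which removes most burn-in
  drift. Everything else updates conjugately with the latents as the
  response.

Reference chain settings (`mcmc_settings()`) are 1,500,000 iterations,
500,000 burn-in, thinning 100 — 10,000 stored draws. The test suite and
the acceptance script use reduced chains (2,500–60,000 iterations depending
on the job); these are stated where used and were chosen so that the
quantities each check needs (posterior means and 95% intervals of variance
components) are stable at the precision being asserted. The intercept of
the binary model mixes slowest; its effective sample size is the reason the
reference settings are as long as they are.

For conjugate-theory verification, `fit_gaussian_lmm(fixed_variances =)`
pins chosen variance components: the conditioned chain then samples a
multivariate normal posterior with a closed form that the test suite
compares against (moments and Kolmogorov–Smirnov).

## The generative model and its calibration

`simulate_assay()` draws, for each response independently, centred normal
group effects for population, host, population-by-host, culture and brood,
builds the linear predictor, and then generates survival as
`Bernoulli(plogis(eta))` and the Gaussian responses with their residual SD,
truncated at zero by redrawing the residual (capped at 1000 attempts; at
the default parameters a negative draw is vanishingly rare, so the cap is a
safety net). Sex is Bernoulli(1/2), applied as ±half the sex difference in
mass, and recorded for survivors only. Responses share no random effects —
each draws its own — so cross-response correlations are absent by
construction.

Defaults (`generative_params()`) are calibrated to the reference assay:

* survival: intercept −2.29; variances 0.046 (population), 2.09 (host),
  0.87 (interaction), 0.0005 (culture) on the logit scale. These are the
  fitted posterior means of the reference analysis; `plogis(-2.29) = 0.092`
  and, after averaging the logit-normal over the group variances, the
  implied grand survival is ≈ 0.17, matching the observed low survival.
* mass: intercept 26.3 mg; variances 0.68 / 33.4 / 9.3 / 0.009; sex
  difference 1.2 mg; residual variance 14, chosen so the marginal SD of
  simulated masses reproduces the observed descriptive SD (7.6 mg).
* development time: intercept 33.9 d; variances 68.7 / 50.8 / 8.6 / 0.008.
  Here the same calibration rule is **unsatisfiable**: the among-group
  components alone already exceed the observed descriptive variance
  (6.5² = 42.25 d²), an artefact of using posterior means of skewed,
  few-level variance posteriors as generative truth. The residual is set
  to 10 d² (a within-culture SD of ≈ 3.2 d, realistic for larvae reared
  together), and the marginal SD of simulated development times
  consequently exceeds the descriptive one. Downstream, this same
  skew-inflation means simulated dev-time population shares sit above the
  reference share.
* brood variance defaults to 0: the fitted models contain no brood term,
  and the design-evaluation module raises it explicitly.

What the generator deliberately does **not** emulate: mortality is
independent across individuals (no cannibalism or density dependence,
although the rearing literature suggests both occur), there are no
whole-culture failures, host treatments are not staggered in calendar time,
and foliage age does not drift. Tests passing on simulated data therefore
validate the statistical machinery under the stated hierarchical model,
not the biology of any particular rearing room.

## Brood structure and pseudoreplication

A finding worth stating explicitly. Under the rearing protocol's
assignment — every individual's brood drawn uniformly from its population's
pool, independently of culture — individuals are exchangeable within a
population, and unmodelled brood variance creates *no* among-culture
structure at all: the among-culture variance contributed by brood
composition is exactly offset by the reduced within-culture mixture
variance. Brood effects then act as pure individual-level noise, which on
the logit scale only *attenuates* the focal variance estimates. That is
the benign, conservative regime: the mixed-brood design is robust exactly
as its users hope.

Pseudoreplication with teeth requires brood membership to be *clustered*
within cultures — e.g. batch-wise handling where each culture is stocked
from a few broods. `simulate_assay(broods_per_culture = k)` and the same
argument of `scenario_spec()` create that regime (with `k = 1`, brood
effects become culture-level effects), and there the test suite verifies
that the model's culture variance absorbs the brood variance.

The design-evaluation module (`run_scenario()`) crosses among-brood
variance levels with focal host-effect settings (null: zero host variance;
alternative: a supplied value), simulates, drops the brood column, fits the
survival model at reduced settings, and aggregates bias, RMSE, coverage and
the positive-call rate with Monte-Carlo standard errors
(`summarize_grid()`).

### Significance calls

Variance posteriors are strictly positive, so no credible interval can
touch zero; a "significant component" needs an explicit rule. The package's
rule (`positive_call()`) is: call the component positive when the lower
bound of the 95% HPD interval of its *variance share* exceeds a small
threshold `epsilon_share` (default 0.01). The threshold can be calibrated
on null simulations (`calibrate_epsilon()`): take the (1 − alpha) quantile
of the null distribution of HPD share lower bounds, after which the null
call rate equals alpha by construction — verified at alpha = 0.05 with two
independent batches of 200 null replicates in the acceptance suite. The
rule is this package's reconstruction of "significance" for variance
components, not a claim about any particular published protocol.

## Posterior summaries and derived quantities

* **Variance shares** are computed within each stored draw (component over
  the total including the residual — fixed, for the binary model) and then
  summarised; a mean of draw-wise shares is not the ratio of posterior
  means, and for skewed posteriors the difference is material. No logistic
  distribution variance (pi²/3) is added: the partition lives on the link
  scale of the fitted model, whose residual is the fixed latent variance.
  `include_residual = FALSE` switches to partitioning among group terms
  only.
* **Treatment predictions** apply the inverse link to the intercept plus
  the requested group effects; unrequested random terms (culture, sex, and
  population for marginal host predictions) are set to zero — the
  conditional-mode convention. For host-level predictions,
  `marginal = "average"` instead averages the inverse-linked cell
  predictions over populations within each draw; both conventions are
  available because which one a published per-host figure uses is usually
  unstated.
* **Intervals** are highest-posterior-density (`hpd_interval()`: shortest
  window over the sorted draws), and effective sample sizes use Geyer's
  initial-positive-sequence estimator — both implemented here and
  cross-checked against an independent implementation in the tests.
* **Development rate** is the draw-wise ratio of mass to development-time
  predictions, paired by stored-draw index. The three models are fitted
  independently, so any pairing is valid; index pairing with equal chain
  settings keeps the propagation purely Monte Carlo. The Gaussian model is
  unbounded, so a far-tail dev-time prediction can be non-positive; the
  default contract aborts with the index, and the pipeline uses the
  documented `on_nonpositive = "drop"` policy (remove those stored draws,
  with a count) on the grounds that they are unphysical extrapolations.
* **Projected fitness** is survival × fecundity(mass), with optional
  eclosion-survival and proportion-female factors (off by default). The
  shipped fecundity is a placeholder — the identity line through the
  origin, 1 egg/mg, floored at zero — because the empirically derived
  mass-fecundity coefficients live in supplementary material not
  distributed here. Relative comparisons between treatment groups are
  unaffected by a linear rescaling; absolute egg numbers are not meaningful
  until real coefficients are supplied via `fitness_config()`.
* When a treatment group is absent from one model (most commonly a host on
  which nothing survived, so the mass model never saw it), derived metrics
  are defined on the groups shared by all contributing models
  (`align_prediction_draws()`, which names what it drops).

## Local adaptation

`local_vs_foreign()` and `home_vs_away()` evaluate the two standard
criteria on cell-level prediction (or derived-metric) draws against a map
of locally abundant hosts per population. Both are rank-based within draws,
hence invariant to monotone transformations of the metric. The shipped
`default_flora_map()` encodes prose habitat descriptions of the four
collection sites (Devon: oak; Edinburgh: oak, sycamore; Buckinghamshire:
apple, cherry, hawthorn; Suffolk: oak, birch, sycamore) and is flagged as
an interpretation — supply your own when it matters. The home-vs-away
output carries a standing caveat: when environments differ strongly in
average quality, that criterion misleads, and it should not be read as a
definitive test. Outputs are posterior probabilities, not verdicts; no
numeric threshold for "locally adapted" is imposed.

## Problem sizes used by the test suite

Chosen as a balance between the precision each check asserts and desk-scale
runtimes, and stated here as package decisions: conjugate-oracle checks on
a 20-group one-way layout (1000 retained draws); parameter recovery on 100
synthetic assays of 1080 larvae at the reference-scale development-time
parameters (6000-iteration chains); null calibration with 2 × 200
replicates of 720-larva assays; host-variance recovery with 12 replicate
full-size (3600) survival fits; and a single full-size synthetic benchmark
analysed with 30,000-iteration chains. The acceptance script averages 8
replicate full-size assays.

One honest caveat from the recovery experiments: the culture variance
component's generative value (≈ 0.01 of the residual) is far below what
any design of this shape can resolve, so its posterior is prior-dominated,
its HPD interval essentially always contains the truth, and its empirical
coverage saturates near 100% — above, not inside, the nominal band a
well-identified component shows. That is a structural property of tiny
variance components under weak priors, not a sampler defect; the
population, host and interaction components show calibrated-to-conservative
coverage (92–97% in the shipped experiment).

## Known limitations

* Scalar (uncorrelated) random effects only; no multivariate
  population-by-response structure, no REML/ML fitting, no model
  comparison (DIC/WAIC).
* The binary model's intercept mixes slowly under the latent random-walk
  scheme; long chains (or a future blocked/re-centred update) are the
  remedy.
* Reading XLSX requires `readxl`; writing is CSV/JSON only.
* The generator's independence assumptions (above) mean design-evaluation
  conclusions speak to the statistical design, not to density-dependent
  biology such as cannibalism.
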