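# hostassay

Bayesian analysis of group-reared, multi-population, multi-host insect
performance assays.

`hostassay` is built for common-garden experiments in which larvae from
several source populations are reared on a panel of host plants in small
group cultures, and performance is scored as survival to pupation, pupal
mass, and development time. The motivating system is the winter moth
(*Operophtera brumata*), a highly polyphagous spring-feeding caterpillar: 4
populations × 9 host plants × 100 larvae per cell, reared in mixed-brood
cultures of 20 (3600 caterpillars). The package serves people who run or
evaluate such assays: it simulates the full hierarchical design (including
brood structure the fitted models cannot see), fits the variance-component
models from scratch, and derives the downstream quantities a host-use study
reports.

## The models

Each performance response is modelled separately with an intercept and
random intercepts on the link scale:

```
eta_i = beta0 + u_pop[p(i)] + u_host[h(i)] + u_pop:host[ph(i)] + u_culture[c(i)]
u_* ~ N(0, sigma2_*)
```

* **Survival** — binary-logit: `surv_i ~ Bernoulli(logit^-1(l_i))` with a
  latent log-odds `l_i ~ N(eta_i, sigma2_e)` whose residual variance is
  *fixed* (default 1; it is not estimable from binary data). Fitted by
  Metropolis-within-Gibbs: adaptive random-walk updates of the latents
  (tuned to ~44% acceptance during burn-in), conjugate updates for
  everything else.
* **Pupal mass** (mg) and **development time** (days) — Gaussian linear
  mixed models fitted by a fully conjugate Gibbs sampler; the mass model
  adds a two-level `sex` random term (only pupae can be sexed).

Priors: Normal(0, 1e8) on the intercept; scalar inverse-Wishart `(V = 1,
nu = 0.002)` on every variance component; the Gaussian residual gets the
same family. Reference chain settings are 1,500,000 iterations, 500,000
burn-in, thinning 100 (10,000 stored draws).

Posterior draws feed:

* `variance_shares()` — draw-wise link-scale variance partition (component /
  total including the residual), the quantity behind "host plant explains
  X% of variance";
* `treatment_predictions()` / `prediction_draws()` — per-host and per-cell
  performance on the response scale;
* `development_rate()` (mg/day) and `projected_fitness()` (survival ×
  fecundity(mass), eggs/female) — posterior functionals combining models;
* `local_vs_foreign()` / `home_vs_away()` — the two Kawecki–Ebert local
  adaptation criteria evaluated against a map of locally abundant hosts;
* `run_scenario()` / `summarize_grid()` — a simulation framework asking
  what unmodelled brood structure (pseudoreplication) does to bias,
  coverage, false-positive rate and power.

## Worked example

```r
library(hostassay)

design <- assay_design()                      # 4 pops x 9 hosts x 5 cultures of 20
sim <- simulate_assay(design, generative_params(), seed = 1)
dplyr::count(sim, survived)
#>   survived     n
#> 1        0  2822
#> 2        1   778

fit <- fit_binary_glmm(sim, settings = mcmc_settings(30000, 10000, 20, seed = 2))
tidy(fit)
#>   term            type        mean     lower  upper    ess
#> 1 intercept       fixed    -2.88   -4.11     -1.78    6.37
#> 2 host            variance  4.63    0.857    10.4    80.1
#> 3 population      variance  0.141   0.000273  0.621  49.6
#> 4 population:host variance  0.984   0.406     1.76  131.
#> 5 culture         variance  0.0699  0.000685  0.191  26.9
#> 6 residual        variance  1       1         1      NA
```

One simulated assay, generated at the calibrated defaults (survival
intercept −2.29, host variance 2.09, interaction 0.87 on the logit scale):
778/3600 larvae survive (21.6%), and the fitted model attributes most
link-scale variance to host plant, with a clear host-by-population
interaction. The realised host variance estimate (4.63 against a generative
2.09) illustrates how much one draw of nine host effects can scatter — the
credible interval is wide accordingly. The short chain used here keeps the
example fast; the intercept's small effective sample size (6) is the reason
the reference analysis runs 1.5M iterations.

```r
variance_shares(fit)[, 1:4]
#>   component        share share_lower share_upper
#> 1 host            0.629    0.359          0.864
#> 2 population      0.0200   0.0000463      0.0937
#> 3 population:host 0.167    0.0316         0.323
#> 4 culture         0.0118   0.0000765      0.0351
#> 5 residual        0.173    0.0653         0.291

head(treatment_predictions(fit, "host"), 3)
#>   metric level group    mean    lower  upper scale
#> 1 surv   host  alder 0.00960 0.000866 0.0220 response
#> 2 surv   host  apple 0.0844  0.0191   0.164  response
#> 3 surv   host  birch 0.642   0.396    0.845  response
```

Host plant carries ~63% of the link-scale variance in this realisation, and
per-host survival predictions range from under 1% to over 60% — the kind of
spread that makes host identity the dominant axis of caterpillar
performance. `run_pipeline()` chains all stages (simulate/load → fit →
partition/predict → derive → local adaptation) into one reproducible run
directory, and `exec/hostassay` exposes the same stages as CLI subcommands.

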