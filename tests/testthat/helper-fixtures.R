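# shared fixtures and short-chain settings; heavier objects are cached per
# test run so several files can reuse one fit

small_design <- function() assay_design(2, 3, 2, 10, broods_per_pop = c(5, 5))

quick_settings <- function(iterations = 4000, burnin = 1000, thin = 3, seed = 1) {
  mcmc_settings(iterations, burnin, thin, seed)
}

# complete Gaussian table (no mortality) on a given design: handy for fitting
# mass/devtime models to every individual
complete_gaussian_assay <- function(design, params, seed) {
  p <- params
  p$survival <- modifyList(p$survival, list(intercept = 20, v_pop = 0, v_host = 0,
                                            v_pop_host = 0, v_culture = 0, v_brood = 0))
  simulate_assay(design, p, seed = seed)
}

# hand-built draws container for tests that need exact, known draws
fake_perf_mcmc <- function(intercept, effects, variances, residual,
                           response = "devtime",
                           family = c("gaussian", "binary-logit")) {
  family <- match.arg(family)
  nd <- length(intercept)
  draws <- tibble::tibble(.draw = seq_len(nd), intercept = intercept)
  for (term in names(variances)) draws[[paste0("var_", term)]] <- variances[[term]]
  draws$var_residual <- residual
  structure(list(
    draws = draws, effects = effects,
    spec = structure(list(response = response, family = family,
                          response_col = response,
                          random_terms = names(effects)), class = "model_spec"),
    priors = prior_spec(), settings = mcmc_settings(nd, 0, 1),
    data = list(n = NA_integer_, levels = lapply(effects, colnames)),
    acceptance = NA_real_), class = "perf_mcmc")
}

# balanced one-way Gaussian layout with known group and residual SDs
one_way_data <- function(n_groups = 20, per_group = 10, seed = 31,
                         sd_between = 1.5, sd_within = 1, intercept = 26.3) {
  set.seed(seed)
  g <- rep(sprintf("g%02d", seq_len(n_groups)), each = per_group)
  u <- rnorm(n_groups, 0, sd_between)
  tibble::tibble(culture = g,
                 pupal_mass_mg = intercept + u[match(g, unique(g))] +
                   rnorm(n_groups * per_group, 0, sd_within))
}

# exact MVN posterior of (intercept, u) for a one-way layout at fixed
# variances: the conjugate-theory oracle the conditioned Gibbs chain must hit
exact_one_way_posterior <- function(dat, sig2_u, sig2_e, prior_var = 1e8) {
  Z <- stats::model.matrix(~ 0 + factor(culture), dat)
  X <- cbind(1, Z)
  A <- crossprod(X) / sig2_e + diag(c(1 / prior_var, rep(1 / sig2_u, ncol(Z))))
  b <- crossprod(X, dat$pupal_mass_mg) / sig2_e
  V <- solve(A)
  list(mean = drop(V %*% b), sd = sqrt(diag(V)))
}

the_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = the_cache)) {
    assign(key, force(expr), envir = the_cache)
  }
  get(key, envir = the_cache)
}

# one moderately informative survival fit on the small design, shared across
# test files
cached_surv_fit <- function() {
  cached("surv_fit", {
    sim <- simulate_assay(small_design(), generative_params(), seed = 7)
    fit_binary_glmm(sim, settings = quick_settings(6000, 2000, 4, seed = 7))
  })
}

cached_mass_fit <- function() {
  cached("mass_fit", {
    sim <- complete_gaussian_assay(small_design(), generative_params(), seed = 8)
    fit_gaussian_lmm(sim, model_spec("mass"),
                     settings = quick_settings(6000, 2000, 4, seed = 8))
  })
}

cached_devtime_fit <- function() {
  cached("devtime_fit", {
    sim <- complete_gaussian_assay(small_design(), generative_params(), seed = 8)
    fit_gaussian_lmm(sim, model_spec("devtime"),
                     settings = quick_settings(6000, 2000, 4, seed = 9))
  })
}
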