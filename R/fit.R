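#' Prior specification for the variance-component models
#'
#' Fixed effects (the intercept) get a diffuse normal prior; each scalar
#' random-effect variance gets an inverse-Wishart prior with scale `V` and
#' degrees of freedom `nu` (equivalently inverse-gamma with shape `nu/2` and
#' rate `nu * V / 2`); the Gaussian residual variance gets the same family.
#' For the binary-logit model the residual variance of the latent log-odds is
#' not estimable and is held fixed at `fixed_resid`.
#'
#' @param fixed_mean,fixed_var Normal prior on the intercept. Defaults 0 and
#'   1e8 (effectively flat).
#' @param term_V,term_nu Inverse-Wishart parameters shared by every random
#'   term. Defaults `V = 1`, `nu = 0.002` (weakly informative).
#' @param resid_V,resid_nu Residual-variance prior (Gaussian models).
#' @param fixed_resid Fixed latent residual variance (binary model).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(fixed_mean = 0, fixed_var = 1e8,
                       term_V = 1, term_nu = 0.002,
                       resid_V = 1, resid_nu = 0.002,
                       fixed_resid = 1) {
  stopifnot(fixed_var > 0, term_V > 0, term_nu > 0,
            resid_V > 0, resid_nu > 0, fixed_resid > 0)
  structure(list(fixed_mean = fixed_mean, fixed_var = fixed_var,
                 term_V = term_V, term_nu = term_nu,
                 resid_V = resid_V, resid_nu = resid_nu,
                 fixed_resid = fixed_resid),
            class = "prior_spec")
}

#' MCMC run settings
#'
#' @param iterations Total iterations. The reference analysis used 1,500,000.
#' @param burnin Burn-in iterations discarded (reference: 500,000).
#' @param thin Thinning interval (reference: 100, giving 10,000 stored draws).
#' @param seed Integer seed making the whole fit deterministic.
#' @return An object of class `mcmc_settings` with an `n_stored` field equal
#'   to `(iterations - burnin) %/% thin`.
#' @export
mcmc_settings <- function(iterations = 1500000, burnin = 500000, thin = 100,
                          seed = 1) {
  stopifnot(iterations >= 1, burnin >= 0, burnin < iterations, thin >= 1)
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed),
                 n_stored = as.integer((iterations - burnin) %/% thin)),
            class = "mcmc_settings")
}

#' Model specification for one performance response
#'
#' Encodes the random-effect structure of the three fitted models: survival
#' and development time use population, host, their interaction, and rearing
#' culture; pupal mass additionally includes sex as a two-level random term
#' (sex can only be determined on pupae, so it cannot enter the survival or
#' development-time models). The only fixed term is the intercept.
#'
#' @param response One of `"surv"`, `"mass"`, `"devtime"`.
#' @param random_terms Optional character vector overriding the default
#'   terms, drawn from `population`, `host`, `population:host`, `culture`,
#'   `sex`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response = c("surv", "mass", "devtime"),
                       random_terms = NULL) {
  response <- match.arg(response)
  default_terms <- c("host", "population", "population:host", "culture")
  if (response == "mass") default_terms <- c(default_terms, "sex")
  random_terms <- random_terms %||% default_terms
  allowed <- c("population", "host", "population:host", "culture", "sex")
  bad <- setdiff(random_terms, allowed)
  if (length(bad)) abort(sprintf("unknown random term(s): %s", paste(bad, collapse = ", ")))
  if (response %in% c("surv", "devtime") && "sex" %in% random_terms) {
    abort("sex cannot be a term in the survival or development-time models (larvae cannot be sexed)")
  }
  structure(list(response = response,
                 family = if (response == "surv") "binary-logit" else "gaussian",
                 response_col = switch(response, surv = "survived",
                                       mass = "pupal_mass_mg",
                                       devtime = "dev_time_days"),
                 random_terms = random_terms),
            class = "model_spec")
}

# build the integer index matrix for the sampler; terms may include the
# population:host interaction, which is constructed on the fly
build_terms <- function(data, random_terms) {
  cols <- lapply(random_terms, function(term) {
    if (term == "population:host") {
      if (!all(c("population", "host") %in% names(data))) {
        abort("population:host term requires `population` and `host` columns")
      }
      paste(data$population, data$host, sep = ":")
    } else {
      if (!term %in% names(data)) abort(sprintf("random term '%s' names no column in the data", term))
      as.character(data[[term]])
    }
  })
  levels <- lapply(cols, function(x) sort(unique(x)))
  for (i in seq_along(random_terms)) {
    if (length(levels[[i]]) < 2) {
      abort(sprintf("random term '%s' has a single level; it cannot be estimated", random_terms[i]))
    }
  }
  G <- if (length(cols)) {
    do.call(cbind, lapply(seq_along(cols), function(i) {
      match(cols[[i]], levels[[i]]) - 1L
    }))
  } else {
    matrix(integer(0), nrow = nrow(data), ncol = 0)
  }
  storage.mode(G) <- "integer"
  list(G = G, levels = levels)
}

new_perf_mcmc <- function(raw, spec, priors, settings, levels, data_info,
                          residual_draws, acceptance = NA_real_) {
  nstore <- length(raw$intercept)
  vars <- raw$variances
  draws <- tibble::tibble(.draw = seq_len(nstore), intercept = raw$intercept)
  for (i in seq_along(spec$random_terms)) {
    draws[[paste0("var_", spec$random_terms[i])]] <- vars[, i]
  }
  draws$var_residual <- residual_draws
  effects <- raw$effects
  names(effects) <- spec$random_terms
  for (i in seq_along(effects)) colnames(effects[[i]]) <- levels[[i]]
  structure(list(draws = draws, effects = effects, spec = spec,
                 priors = priors, settings = settings,
                 data = data_info, acceptance = acceptance),
            class = "perf_mcmc")
}

#' Fit a Gaussian variance-component model by Gibbs sampling
#'
#' Single-site Gibbs sampler with fully conjugate updates: the intercept and
#' each block of group effects are drawn from their normal full conditionals,
#' and each variance component (and the residual variance) from its scaled
#' inverse-chi-square full conditional under the `(V, nu)` inverse-Wishart
#' prior. Rows with a missing response are dropped with a message (for pupal
#' mass and development time these are the non-survivors).
#'
#' @param data A data frame of individual records.
#' @param spec A [model_spec()] (or a response name understood by it).
#' @param priors A [prior_spec()].
#' @param settings An [mcmc_settings()].
#' @param fixed_variances Optional named list pinning chosen variance
#'   components (names among the random terms, plus `"residual"`) to fixed
#'   values instead of sampling them — used for conjugate-theory checks.
#' @return A `perf_mcmc` object: stored draws of the intercept and variance
#'   components (tibble `$draws`), per-term group-effect draw matrices
#'   (`$effects`), and the specification metadata.
#' @export
fit_gaussian_lmm <- function(data, spec = model_spec("mass"),
                             priors = prior_spec(),
                             settings = mcmc_settings(),
                             fixed_variances = NULL) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "gaussian") abort("fit_gaussian_lmm() requires a gaussian response")
  ycol <- spec$response_col
  if (!ycol %in% names(data)) abort(sprintf("response column '%s' not found", ycol))

  keep <- !is.na(data[[ycol]])
  if (!all(keep)) {
    message(sprintf("dropping %d row(s) with missing %s", sum(!keep), ycol))
    data <- data[keep, , drop = FALSE]
  }
  y <- as.numeric(data[[ycol]])
  if (length(y) < 2 || sd(y) == 0) abort("response has zero variance; nothing to fit")

  bt <- build_terms(data, spec$random_terms)
  T <- length(spec$random_terms)
  fixed_variances <- fixed_variances %||% list()
  fix_term <- spec$random_terms %in% names(fixed_variances)
  fix_val <- vapply(spec$random_terms, function(t)
    if (t %in% names(fixed_variances)) as.numeric(fixed_variances[[t]]) else 0,
    numeric(1))
  fix_resid <- "residual" %in% names(fixed_variances)

  set.seed(settings$seed)
  raw <- gibbs_gaussian_cpp(
    y, bt$G, vapply(bt$levels, length, integer(1)),
    priors$fixed_mean, priors$fixed_var,
    rep(priors$term_nu, T), rep(priors$term_V, T),
    priors$resid_nu, priors$resid_V,
    settings$iterations, settings$burnin, settings$thin,
    fix_term, fix_val,
    fix_resid, if (fix_resid) as.numeric(fixed_variances$residual) else 1)

  new_perf_mcmc(raw, spec, priors, settings, bt$levels,
                data_info = list(n = length(y), response_mean = mean(y),
                                 levels = setNames(bt$levels, spec$random_terms)),
                residual_draws = raw$residual)
}

#' Fit the binary-logit variance-component model
#'
#' Latent-variable Metropolis-within-Gibbs sampler for a Bernoulli response.
#' Every individual carries a latent log-odds whose likelihood is
#' `Bernoulli(plogis(l))` and whose prior is normal around the linear
#' predictor with a *fixed* residual variance (default 1; it is not
#' estimable from binary data). Latents are updated by an adaptive
#' random-walk Metropolis step (proposal scale tuned towards 44% acceptance
#' during burn-in only, then frozen); the intercept, group effects and
#' variance components are then updated conjugately exactly as in the
#' Gaussian sampler, with the latents as the response.
#'
#' @inheritParams fit_gaussian_lmm
#' @return A `perf_mcmc` object; `$draws$var_residual` is the constant fixed
#'   value, and `$acceptance` records the post-burn-in Metropolis acceptance
#'   rate.
#' @export
fit_binary_glmm <- function(data, spec = model_spec("surv"),
                            priors = prior_spec(),
                            settings = mcmc_settings()) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "binary-logit") abort("fit_binary_glmm() requires the binary survival response")
  ycol <- spec$response_col
  if (!ycol %in% names(data)) abort(sprintf("response column '%s' not found", ycol))
  y <- data[[ycol]]
  if (anyNA(y) || !all(y %in% c(0, 1))) abort("response must be strictly 0/1 with no missing values")
  if (all(y == 0) || all(y == 1)) {
    abort("response is all-0 or all-1: the intercept is unidentifiable without an informative prior")
  }
  y <- as.integer(y)

  bt <- build_terms(data, spec$random_terms)
  T <- length(spec$random_terms)

  set.seed(settings$seed)
  raw <- gibbs_binary_cpp(
    y, bt$G, vapply(bt$levels, length, integer(1)),
    priors$fixed_mean, priors$fixed_var,
    rep(priors$term_nu, T), rep(priors$term_V, T),
    priors$fixed_resid,
    settings$iterations, settings$burnin, settings$thin,
    1.0)

  fit <- new_perf_mcmc(raw, spec, priors, settings, bt$levels,
                       data_info = list(n = length(y), response_mean = mean(y),
                                        levels = setNames(bt$levels, spec$random_terms)),
                       residual_draws = rep(priors$fixed_resid, length(raw$intercept)),
                       acceptance = raw$acceptance)
  fit$pred_prop <- raw$pred_prop
  fit
}

#' Fit one of the three performance models
#'
#' Front door dispatching on the response: `"surv"` fits the binary-logit
#' model via [fit_binary_glmm()]; `"mass"` and `"devtime"` fit Gaussian
#' models via [fit_gaussian_lmm()] (on survivors with a recorded value).
#'
#' @param data Assay table (one row per individual).
#' @param response `"surv"`, `"mass"` or `"devtime"`.
#' @param priors A [prior_spec()].
#' @param settings An [mcmc_settings()].
#' @param ... Passed on to the underlying fitting function.
#' @return A `perf_mcmc` object.
#' @examples
#' \donttest{
#' sim <- simulate_assay(assay_design(2, 3, 2, 10, c(5, 5)),
#'                       generative_params(), seed = 1)
#' fit <- fit_performance_model(sim, "surv",
#'                              settings = mcmc_settings(2000, 500, 5, seed = 1))
#' tidy(fit)
#' }
#' @export
fit_performance_model <- function(data, response = c("surv", "mass", "devtime"),
                                  priors = prior_spec(),
                                  settings = mcmc_settings(), ...) {
  response <- match.arg(response)
  spec <- model_spec(response)
  if (response == "surv") {
    fit_binary_glmm(data, spec, priors, settings, ...)
  } else {
    fit_gaussian_lmm(data, spec, priors, settings, ...)
  }
}

#' @export
print.perf_mcmc <- function(x, ...) {
  cat(sprintf("<perf_mcmc> %s model (%s), %d individuals\n",
              x$spec$response, x$spec$family, x$data$n))
  cat(sprintf("  %d stored draws (%d iterations, %d burn-in, thin %d, seed %d)\n",
              nrow(x$draws), x$settings$iterations, x$settings$burnin,
              x$settings$thin, x$settings$seed))
  if (!is.na(x$acceptance)) {
    cat(sprintf("  latent Metropolis acceptance: %.2f\n", x$acceptance))
  }
  print(summarize_model(x))
  invisible(x)
}
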