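#' Generative parameters for the assay simulator
#'
#' Defines the data-generating process on the link scale for the three
#' performance responses. Each response has an intercept and variance
#' components for population, host, population-by-host, culture and brood
#' effects; the Gaussian responses (pupal mass in mg, development time in
#' days) additionally carry a residual variance, and mass carries a fixed
#' sex difference. Survival operates on the logit scale: the latent log-odds
#' is the sum of the intercept and the group effects, and the binary outcome
#' is Bernoulli(plogis(latent)).
#'
#' Defaults are calibrated to the reference assay: the survival intercept
#' (-2.29) and the variance components are the posterior means of the fitted
#' variance-component models, the mass residual variance is chosen so that
#' the marginal SD of simulated masses matches the observed descriptive SD
#' (7.6 mg), and the sex difference (1.2 mg) matches the observed
#' female-male contrast (26.8 vs 25.6 mg). Brood variance defaults to zero
#' (the fitted models contain no brood term); the design-evaluation
#' simulations raise it explicitly.
#'
#' @param survival,mass,devtime Named lists overriding individual defaults;
#'   see the defaults in the function signature for the available fields.
#' @param fitness A [fitness_config()] carried along for downstream fitness
#'   projection.
#' @return An object of class `generative_params`.
#' @export
generative_params <- function(survival = list(), mass = list(),
                              devtime = list(), fitness = fitness_config()) {
  def <- list(
    survival = list(intercept = -2.29, v_pop = 0.046, v_host = 2.09,
                    v_pop_host = 0.87, v_culture = 0.0005, v_brood = 0),
    mass = list(intercept = 26.3, v_pop = 0.68, v_host = 33.4,
                v_pop_host = 9.3, v_culture = 0.009, v_brood = 0,
                v_resid = 14, sex_effect = 1.2, prop_female = 0.5),
    devtime = list(intercept = 33.9, v_pop = 68.7, v_host = 50.8,
                   v_pop_host = 8.6, v_culture = 0.008, v_brood = 0,
                   v_resid = 10)
  )
  check_extra <- function(user, ref, what) {
    bad <- setdiff(names(user), names(ref))
    if (length(bad)) abort(sprintf("unknown %s parameter(s): %s", what,
                                   paste(bad, collapse = ", ")))
  }
  check_extra(survival, def$survival, "survival")
  check_extra(mass, def$mass, "mass")
  check_extra(devtime, def$devtime, "devtime")
  p <- list(survival = modifyList(def$survival, survival),
            mass = modifyList(def$mass, mass),
            devtime = modifyList(def$devtime, devtime),
            fitness = fitness)
  validate_params(p)
  structure(p, class = "generative_params")
}

validate_params <- function(p) {
  for (resp in c("survival", "mass", "devtime")) {
    x <- p[[resp]]
    vs <- x[grepl("^v_", names(x))]
    if (any(vapply(vs, function(v) !is.finite(v) || v < 0, logical(1)))) {
      abort(sprintf("all %s variance components must be finite and >= 0", resp))
    }
    if (!is.finite(x$intercept)) abort(sprintf("%s intercept must be finite", resp))
  }
  pf <- p$mass$prop_female
  if (!is.finite(pf) || pf < 0 || pf > 1) abort("prop_female must be in [0, 1]")
  invisible(p)
}

#' @export
print.generative_params <- function(x, ...) {
  cat("<generative_params>\n")
  for (resp in c("survival", "mass", "devtime")) {
    cat(sprintf("  %s: %s\n", resp,
                paste(names(x[[resp]]), signif(unlist(x[[resp]]), 4),
                      sep = "=", collapse = ", ")))
  }
  invisible(x)
}

#' Read generative parameters from a configuration file
#'
#' Accepts a JSON or YAML file (chosen by extension) whose top-level keys are
#' any of `survival`, `mass`, `devtime` and `fitness`; omitted entries keep
#' the package defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [generative_params()] object.
#' @export
params_from_file <- function(path) {
  cfg <- read_config(path)
  fit <- if (!is.null(cfg$fitness)) do.call(fitness_config, cfg$fitness) else fitness_config()
  generative_params(survival = cfg$survival %||% list(),
                    mass = cfg$mass %||% list(),
                    devtime = cfg$devtime %||% list(),
                    fitness = fit)
}

read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configuration requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    abort(sprintf("unsupported config extension '%s' (use .json or .yaml)", ext))
  }
}
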