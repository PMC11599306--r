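#' Fecundity configuration for fitness projection
#'
#' Projected absolute individual fitness multiplies a treatment group's
#' survival probability by the fecundity (eggs per female) implied by its
#' pupal mass. The mass-to-eggs mapping is configurable: a linear function,
#' a power law (`"log-linear"`: linear on log-log scale), or a user table
#' interpolated linearly. The shipped default is a deliberate placeholder —
#' the identity line through the origin (1 egg per mg) — because the
#' empirically derived mass-fecundity coefficients live in supplementary
#' material not distributed with this package; substitute your own
#' coefficients for absolute (rather than relative) projections.
#'
#' @param family `"linear"` (`eggs = intercept + slope * mass`),
#'   `"log-linear"` (`eggs = exp(intercept + slope * log(mass))`), or
#'   `"table"` (linear interpolation of `table$mass_mg` vs `table$eggs`).
#' @param slope,intercept Coefficients for the parametric families.
#' @param table Data frame with columns `mass_mg` and `eggs` (family
#'   `"table"`).
#' @param prop_female Optional proportion-female factor multiplied into the
#'   projection (default `NULL`: off, fitness is per female).
#' @param eclosion_survival Optional survival-to-eclosion factor in [0, 1]
#'   (default 1: off).
#' @return An object of class `fitness_config` containing a vectorised
#'   `fecundity(mass)` function.
#' @export
fitness_config <- function(family = c("linear", "log-linear", "table"),
                           slope = 1, intercept = 0, table = NULL,
                           prop_female = NULL, eclosion_survival = 1) {
  family <- match.arg(family)
  if (!is.null(prop_female) && (prop_female < 0 || prop_female > 1)) {
    abort("prop_female must be in [0, 1]")
  }
  if (eclosion_survival < 0 || eclosion_survival > 1) {
    abort("eclosion_survival must be in [0, 1]")
  }
  if (family == "linear") {
    if (slope < 0) abort("fecundity must be non-decreasing in mass")
    if (intercept + slope * 1 < 0) {
      abort("fecundity must be finite and non-negative over the plausible mass range (1-100 mg)")
    }
  }
  # the linear family is floored at zero so that posterior tail draws below
  # the plausible mass range project to zero eggs rather than negative ones
  fecundity <- switch(family,
    "linear" = function(mass) pmax(0, intercept + slope * mass),
    "log-linear" = function(mass) exp(intercept + slope * log(mass)),
    "table" = {
      if (is.null(table) || !all(c("mass_mg", "eggs") %in% names(table))) {
        abort("family 'table' needs a data frame with columns mass_mg and eggs")
      }
      if (any(table$eggs < 0)) abort("fecundity table contains negative egg counts")
      if (is.unsorted(table$eggs[order(table$mass_mg)])) {
        abort("fecundity must be non-decreasing in mass")
      }
      approxfun(table$mass_mg, table$eggs, rule = 2)
    })
  # non-negativity / monotonicity sanity check over the plausible mass range
  grid <- fecundity(seq(1, 100, by = 1))
  if (is.unsorted(grid)) abort("fecundity must be non-decreasing in mass")
  if (any(!is.finite(grid)) || any(grid < 0)) {
    abort("fecundity must be finite and non-negative over the plausible mass range (1-100 mg)")
  }
  structure(list(family = family, slope = slope, intercept = intercept,
                 table = table, prop_female = prop_female,
                 eclosion_survival = eclosion_survival,
                 fecundity = fecundity),
            class = "fitness_config")
}

#' Restrict prediction draws to their shared treatment groups
#'
#' The three performance models are fitted to different subsets of the data
#' (the Gaussian models see survivors only), so a treatment group can be
#' missing from one model — most commonly a host on which nothing survived.
#' Derived metrics are then defined only on the groups present in every
#' contributing model; this helper subsets a set of prediction-draw matrices
#' to those shared groups, with a message naming any group dropped.
#'
#' @param ... Named prediction-draw matrices (see [prediction_draws()]).
#' @return A named list of matrices with identical column sets.
#' @export
align_prediction_draws <- function(...) {
  mats <- list(...)
  stopifnot(length(mats) >= 2, all(vapply(mats, is.matrix, logical(1))))
  shared <- Reduce(intersect, lapply(mats, colnames))
  if (length(shared) == 0) abort("no treatment group is shared by all draw sets")
  dropped <- setdiff(unique(unlist(lapply(mats, colnames))), shared)
  if (length(dropped)) {
    message(sprintf("dropping group(s) absent from some model: %s",
                    paste(dropped, collapse = ", ")))
  }
  lapply(mats, function(m) m[, shared, drop = FALSE])
}

check_aligned <- function(a, b, what_a, what_b) {
  if (!is.matrix(a) || !is.matrix(b)) abort("draw inputs must be matrices of draws by groups (see prediction_draws())")
  if (nrow(a) != nrow(b)) {
    abort(sprintf("%s and %s have different stored-draw counts (%d vs %d); refit with matched chain settings",
                  what_a, what_b, nrow(a), nrow(b)))
  }
  if (ncol(a) != ncol(b) || !identical(colnames(a), colnames(b))) {
    abort(sprintf("%s and %s cover different treatment groups", what_a, what_b))
  }
  invisible(TRUE)
}

new_derived_posterior <- function(draws_matrix, metric, prob = 0.95) {
  grand <- rowMeans(draws_matrix)
  full <- cbind(draws_matrix, overall = grand)
  summary <- purrr::map_dfr(colnames(full), function(g) {
    ci <- hpd_interval(full[, g], prob)
    tibble::tibble(metric = metric, group = g, mean = mean(full[, g]),
                   lower = ci[["lower"]], upper = ci[["upper"]])
  })
  structure(list(summary = summary, draws = full, metric = metric),
            class = "derived_posterior")
}

#' @export
print.derived_posterior <- function(x, ...) {
  cat(sprintf("<derived_posterior> %s, %d groups + overall, %d draws\n",
              x$metric, ncol(x$draws) - 1L, nrow(x$draws)))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.derived_posterior <- function(x, ...) x$summary

#' Posterior development rate (mg/day)
#'
#' Draw-wise ratio of the pupal-mass prediction to the development-time
#' prediction within each treatment group; the draw sequences are paired by
#' stored-draw index (the models are fitted independently, so any pairing is
#' valid, and index pairing keeps the propagation purely Monte Carlo). The
#' `overall` group is the draw-wise mean of the per-group rates — note that
#' a mean of ratios is not the ratio of grand means.
#'
#' @param mass_draws,devtime_draws Prediction-draw matrices from
#'   [prediction_draws()] for the mass and development-time fits, with equal
#'   draw counts and identical group columns.
#' @param prob Credible-interval mass.
#' @param on_nonpositive What to do with draws in which a development-time
#'   prediction is not positive (possible in the far posterior tail, since
#'   the Gaussian model is unbounded): `"abort"` (default) stops with the
#'   offending index; `"drop"` removes those stored draws from every group
#'   with a message, treating them as unphysical extrapolations.
#' @return A `derived_posterior`: summary tibble (`metric`, `group`, `mean`,
#'   `lower`, `upper`) plus the draw matrix.
#' @export
development_rate <- function(mass_draws, devtime_draws, prob = 0.95,
                             on_nonpositive = c("abort", "drop")) {
  on_nonpositive <- match.arg(on_nonpositive)
  check_aligned(mass_draws, devtime_draws, "mass draws", "devtime draws")
  if (any(devtime_draws <= 0)) {
    if (on_nonpositive == "abort") {
      bad <- which(devtime_draws <= 0)[1]
      abort(sprintf("non-positive development-time draw at index %d", bad))
    }
    keep <- rowSums(devtime_draws <= 0) == 0
    if (!any(keep)) abort("no draw has all-positive development-time predictions")
    message(sprintf("dropping %d of %d draws with non-positive development-time predictions",
                    sum(!keep), length(keep)))
    mass_draws <- mass_draws[keep, , drop = FALSE]
    devtime_draws <- devtime_draws[keep, , drop = FALSE]
  }
  new_derived_posterior(mass_draws / devtime_draws, "rate", prob)
}

#' Posterior projected fitness (eggs per female)
#'
#' Per draw and per treatment group, projected fitness is the survival
#' probability times the fecundity implied by the pupal mass, times the
#' optional eclosion-survival and proportion-female factors of the
#' [fitness_config()]. The `overall` group is the draw-wise arithmetic mean
#' over treatment groups.
#'
#' @param survival_draws,mass_draws Aligned prediction-draw matrices from the
#'   survival and mass fits (survival on the probability scale).
#' @param config A [fitness_config()].
#' @param prob Credible-interval mass.
#' @return A `derived_posterior`.
#' @export
projected_fitness <- function(survival_draws, mass_draws,
                              config = fitness_config(), prob = 0.95) {
  stopifnot(inherits(config, "fitness_config"))
  check_aligned(survival_draws, mass_draws, "survival draws", "mass draws")
  if (any(survival_draws < 0 | survival_draws > 1)) {
    abort("survival draws must be probabilities in [0, 1]")
  }
  eggs <- config$fecundity(mass_draws)
  if (any(eggs < 0)) abort("fecundity returned negative values")
  fit <- survival_draws * eggs * config$eclosion_survival
  if (!is.null(config$prop_female)) fit <- fit * config$prop_female
  dim(fit) <- dim(survival_draws)
  dimnames(fit) <- dimnames(survival_draws)
  new_derived_posterior(fit, "fitness", prob)
}
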