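#' Simulate a complete rearing assay
#'
#' Draws one realisation of the assay under the hierarchical generative
#' model. For every response, independent group effects are drawn for
#' population, host, population-by-host cell, culture and brood, each from a
#' centred normal with the corresponding variance component. Survival is
#' generated as `Bernoulli(plogis(eta))` with `eta` the sum of the survival
#' intercept and its group effects. Survivors then receive a pupal mass
#' (intercept, +/- half the sex difference, group effects, Gaussian residual)
#' and a development time (likewise, without a sex term); both Gaussian
#' responses are truncated at zero by redraw of the residual. Sex is recorded
#' for survivors only, because only pupae can be sexed.
#'
#' Brood membership is part of the generative process but is typically
#' invisible to the fitted models (larvae are reared in mixed-brood
#' cultures); the `brood` column is retained in the output so that
#' design-evaluation simulations can drop it explicitly.
#'
#' @param design An [assay_design()].
#' @param params A [generative_params()].
#' @param seed Integer seed; output is byte-identical for identical
#'   `(design, params, seed)`.
#' @param drop_brood Drop the `brood` column from the returned table.
#' @param broods_per_culture `NULL` (default) assigns every individual's brood
#'   uniformly from its population's pool, as in the rearing protocol — under
#'   that assignment brood effects behave as individual-level noise. An
#'   integer `k` instead stocks each culture from only `k` broods (batch-wise
#'   handling), clustering brood membership within cultures and turning
#'   unmodelled brood variance into genuine pseudoreplication.
#' @return A tibble with one row per individual and columns `id`,
#'   `population`, `host`, `culture`, `brood`, `sex` (`"F"`/`"M"`/`NA`),
#'   `survived` (0/1), `pupal_mass_mg` and `dev_time_days` (both `NA` unless
#'   `survived == 1`).
#' @examples
#' d <- assay_design(2, 3, 2, 10, broods_per_pop = c(5, 5))
#' sim <- simulate_assay(d, generative_params(), seed = 1)
#' table(sim$survived)
#' @export
simulate_assay <- function(design, params = generative_params(), seed,
                           drop_brood = FALSE, broods_per_culture = NULL) {
  stopifnot(inherits(design, "assay_design"))
  if (!inherits(params, "generative_params")) {
    abort("`params` must be a generative_params object")
  }
  set.seed(as.integer(seed))

  layout <- draw_broods(design_layout(design), design, broods_per_culture)
  n <- nrow(layout)
  cell <- paste(layout$population, layout$host, sep = ":")

  group_effect <- function(labels, v) {
    lev <- sort(unique(labels))
    setNames(rnorm(length(lev), 0, sqrt(v)), lev)[labels]
  }
  linpred <- function(p) {
    p$intercept +
      group_effect(layout$population, p$v_pop) +
      group_effect(layout$host, p$v_host) +
      group_effect(cell, p$v_pop_host) +
      group_effect(layout$culture, p$v_culture) +
      group_effect(layout$brood, p$v_brood)
  }

  eta_surv <- linpred(params$survival)
  survived <- rbinom(n, 1, plogis(eta_surv))

  sex <- ifelse(runif(n) < params$mass$prop_female, "F", "M")
  sex[survived == 0] <- NA_character_

  sex_shift <- ifelse(is.na(sex), 0, ifelse(sex == "F", 0.5, -0.5)) *
    params$mass$sex_effect
  mu_mass <- linpred(params$mass) + sex_shift
  mass <- truncated_normal(mu_mass, sqrt(params$mass$v_resid))
  mass[survived == 0] <- NA_real_

  mu_dev <- linpred(params$devtime)
  devt <- truncated_normal(mu_dev, sqrt(params$devtime$v_resid))
  devt[survived == 0] <- NA_real_

  out <- tibble::tibble(
    id = layout$id, population = layout$population, host = layout$host,
    culture = layout$culture, brood = layout$brood, sex = sex,
    survived = survived, pupal_mass_mg = mass, dev_time_days = devt)
  if (drop_brood) out$brood <- NULL
  out
}

# elementwise positive truncation by redraw; at the default parameters a
# negative draw is vanishingly rare, so the attempt cap is a safety net only
truncated_normal <- function(mean, sd, max_attempts = 1000) {
  x <- rnorm(length(mean), mean, sd)
  attempt <- 1
  while (any(bad <- x <= 0)) {
    attempt <- attempt + 1
    if (attempt > max_attempts) {
      abort("positive truncation failed after 1000 redraws; check that the intercept is well above zero relative to the residual SD")
    }
    x[bad] <- rnorm(sum(bad), mean[bad], sd)
  }
  x
}

#' Write or read an assay table as CSV
#'
#' Plain UTF-8 CSV with header
#' `id,population,host,culture,brood,sex,survived,pupal_mass_mg,dev_time_days`
#' (`brood` optional); missing values are written as empty fields. The
#' round-trip `write_assay_csv()` then [read_assay_table()] is lossless.
#'
#' @param data An assay table, as produced by [simulate_assay()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(path)
}
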