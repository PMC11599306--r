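#' Specify a design-evaluation scenario grid
#'
#' The design-evaluation experiment asks what the analysis loses by rearing
#' larvae in mixed-brood cultures without a brood term in the model:
#' datasets are generated *with* brood effects (at each requested
#' among-brood variance) and analysed *without* them — the pseudoreplicated
#' analysis. Cells cross the brood-variance levels with focal host-effect
#' settings (a null cell generates with zero host variance; alternative
#' cells supply a positive value), and each cell is replicated.
#'
#' @param design An [assay_design()].
#' @param params Base [generative_params()]; the scenario overrides the
#'   survival brood and host variances cell by cell.
#' @param brood_levels Numeric vector of among-brood variance levels (link
#'   scale) for the survival response.
#' @param host_levels Numeric vector of focal host-variance settings; `0` is
#'   the null. Default `c(0, 2.09)` — no host effect, and a host effect at
#'   the scale estimated from the reference assay.
#' @param replicates Replicate datasets per cell.
#' @param settings Reduced [mcmc_settings()] used for every replicate fit.
#'   Full-length chains are not desk-scale at hundreds of replicates; the
#'   default (15,000 iterations, 5,000 burn-in, thin 10) is enough for the
#'   variance summaries these cells need.
#' @param epsilon_share Share threshold for [positive_call()].
#' @param prob HPD mass used for intervals and calls.
#' @param broods_per_culture Passed to [simulate_assay()]: `NULL` for the
#'   protocol's uniform assignment (brood effects act as individual noise),
#'   or an integer `k` for batch-wise stocking of each culture from `k`
#'   broods — the clustered regime in which brood variance is genuinely
#'   pseudoreplicating.
#' @param seed Master seed; per-replicate seeds are spawned from it and
#'   recorded in the output.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(design = assay_design(),
                          params = generative_params(),
                          brood_levels = c(0, 0.5, 1),
                          host_levels = c(0, 2.09),
                          replicates = 20,
                          settings = mcmc_settings(15000, 5000, 10, seed = 1),
                          epsilon_share = 0.01, prob = 0.95,
                          broods_per_culture = NULL, seed = 1) {
  stopifnot(inherits(design, "assay_design"),
            inherits(params, "generative_params"),
            replicates >= 1, all(brood_levels >= 0), all(host_levels >= 0))
  structure(list(design = design, params = params,
                 brood_levels = brood_levels, host_levels = host_levels,
                 replicates = as.integer(replicates), settings = settings,
                 epsilon_share = epsilon_share, prob = prob,
                 broods_per_culture = broods_per_culture,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Significance call for a variance component
#'
#' A component is called "positive" when the lower bound of its HPD
#' variance-share interval exceeds a small threshold. Variance posteriors
#' are strictly positive, so their intervals can never include zero exactly;
#' a near-zero share threshold plays the role of the null value. The
#' threshold can be calibrated on null simulations with
#' [calibrate_epsilon()] so that the null call rate matches a nominal level.
#'
#' @param fit A `perf_mcmc` object (or data frame of variance draws).
#' @param component Component name, e.g. `"host"`.
#' @param epsilon_share Share threshold (default 0.01).
#' @param prob HPD mass (default 0.95).
#' @return `TRUE` or `FALSE`.
#' @export
positive_call <- function(fit, component = "host", epsilon_share = 0.01,
                          prob = 0.95) {
  share_hpd_lower(fit, component, prob) > epsilon_share
}

#' @rdname positive_call
#' @export
share_hpd_lower <- function(fit, component = "host", prob = 0.95) {
  shares <- attr(variance_shares(fit, prob), "share_draws")
  if (!component %in% colnames(shares)) {
    abort(sprintf("unknown component '%s' (have: %s)", component,
                  paste(colnames(shares), collapse = ", ")))
  }
  unname(hpd_interval(shares[, component], prob)[["lower"]])
}

#' Calibrate the positive-call threshold on null simulations
#'
#' Given the HPD share lower bounds observed across null-cell replicates
#' (datasets generated with zero focal variance), returns the threshold
#' whose exceedance rate under the null equals the nominal level.
#'
#' @param null_lower_bounds Numeric vector of [share_hpd_lower()] values
#'   from null replicates.
#' @param alpha Nominal false-positive level (default 0.05).
#' @return The calibrated `epsilon_share`.
#' @export
calibrate_epsilon <- function(null_lower_bounds, alpha = 0.05) {
  stopifnot(length(null_lower_bounds) >= 20, alpha > 0, alpha < 1)
  unname(quantile(null_lower_bounds, 1 - alpha, type = 8))
}

#' Run a design-evaluation scenario
#'
#' For every cell (brood-variance level by focal host setting) and
#' replicate: simulate an assay with brood effects, drop the brood column,
#' fit the survival model without a brood term at the reduced chain
#' settings, and record the posterior mean, HPD interval and coverage for
#' every variance component, together with the focal positive/negative call.
#' Replicate fit failures are caught, flagged and excluded (with a count),
#' not fatal.
#'
#' @param spec A [scenario_spec()].
#' @param .progress Emit a message per cell.
#' @return An object of class `scenario_result` with elements `replicates`
#'   (long tibble: one row per replicate by component), `calls` (one row per
#'   replicate), `failures`, and the originating `spec`.
#' @export
run_scenario <- function(spec, .progress = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  cells <- tidyr::expand_grid(brood_var = spec$brood_levels,
                              host_var = spec$host_levels)
  cells$cell <- seq_len(nrow(cells))
  set.seed(spec$seed)
  n_total <- nrow(cells) * spec$replicates
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_total)

  rep_rows <- list(); call_rows <- list(); failures <- 0L
  idx <- 0L
  for (ci in seq_len(nrow(cells))) {
    if (.progress) message(sprintf("cell %d/%d (brood %.3g, host %.3g)",
                                   ci, nrow(cells), cells$brood_var[ci],
                                   cells$host_var[ci]))
    p <- spec$params
    p$survival$v_brood <- cells$brood_var[ci]
    p$survival$v_host <- cells$host_var[ci]
    truth <- c(population = p$survival$v_pop, host = p$survival$v_host,
               "population:host" = p$survival$v_pop_host,
               culture = p$survival$v_culture)
    for (r in seq_len(spec$replicates)) {
      idx <- idx + 1L
      sd_r <- rep_seeds[idx]
      fit <- tryCatch({
        sim <- simulate_assay(spec$design, p, seed = sd_r, drop_brood = TRUE,
                              broods_per_culture = spec$broods_per_culture)
        st <- spec$settings; st$seed <- sd_r
        fit_binary_glmm(sim, model_spec("surv"), settings = st)
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        failures <- failures + 1L
        call_rows[[idx]] <- tibble::tibble(
          cell = ci, brood_var = cells$brood_var[ci],
          host_var = cells$host_var[ci], rep = r, seed = sd_r, ok = FALSE,
          call = NA, share_lower = NA_real_, error = conditionMessage(fit))
        next
      }
      comp_rows <- purrr::map_dfr(names(truth), function(comp) {
        x <- fit$draws[[paste0("var_", comp)]]
        ci_ <- hpd_interval(x, spec$prob)
        tv <- truth[[comp]]
        tibble::tibble(cell = ci, brood_var = cells$brood_var[ci],
                       host_var = cells$host_var[ci], rep = r, seed = sd_r,
                       component = comp, truth = tv,
                       estimate = mean(x),
                       lower = ci_[["lower"]], upper = ci_[["upper"]],
                       covered = tv >= ci_[["lower"]] && tv <= ci_[["upper"]])
      })
      rep_rows[[idx]] <- comp_rows
      call_rows[[idx]] <- tibble::tibble(
        cell = ci, brood_var = cells$brood_var[ci],
        host_var = cells$host_var[ci], rep = r, seed = sd_r, ok = TRUE,
        call = positive_call(fit, "host", spec$epsilon_share, spec$prob),
        share_lower = share_hpd_lower(fit, "host", spec$prob),
        error = NA_character_)
    }
  }
  structure(list(replicates = dplyr::bind_rows(rep_rows),
                 calls = dplyr::bind_rows(call_rows),
                 failures = failures, cells = cells, spec = spec),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %d cells x %d replicates (%d failed)\n",
              nrow(x$cells), x$spec$replicates, x$failures))
  print(summarize_grid(x))
  invisible(x)
}

#' Summarise a scenario grid
#'
#' Long-format summary over scenario cells: per variance component the mean
#' bias, RMSE and coverage of the generative value, and per cell the
#' positive-call rate (false-positive rate in null cells, power in
#' alternative cells), each with a Monte-Carlo standard error. With a single
#' replicate the Monte-Carlo SEs are reported as `NA`.
#'
#' @param result A `scenario_result` from [run_scenario()].
#' @return A tidy tibble, one row per cell by component, with the cell-level
#'   call rate repeated within the cell.
#' @export
summarize_grid <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  if (nrow(result$replicates) == 0) abort("no successful replicates to summarise")
  mc_se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  comp <- result$replicates |>
    dplyr::group_by(.data$cell, .data$brood_var, .data$host_var, .data$component) |>
    dplyr::summarise(
      n = dplyr::n(),
      bias = mean(.data$estimate - .data$truth),
      bias_se = mc_se(.data$estimate - .data$truth),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      coverage = mean(.data$covered),
      coverage_se = {
        p <- mean(.data$covered); n <- dplyr::n()
        if (n > 1) sqrt(p * (1 - p) / n) else NA_real_
      },
      .groups = "drop")
  calls <- result$calls |>
    dplyr::filter(.data$ok) |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(
      n_calls = dplyr::n(),
      positive_rate = mean(.data$call),
      positive_rate_se = {
        p <- mean(.data$call); n <- dplyr::n()
        if (n > 1) sqrt(p * (1 - p) / n) else NA_real_
      },
      .groups = "drop")
  dplyr::left_join(comp, calls, by = "cell")
}
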