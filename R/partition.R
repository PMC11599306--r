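#' Link-scale variance shares
#'
#' Computes, draw by draw, each component's share of the summed link-scale
#' variance — every random-term variance plus the residual variance (fixed,
#' for the binary model) — and summarises the shares by their posterior mean
#' and 95% HPD interval. Because shares are formed within draws, the mean
#' share need not equal the ratio of posterior-mean variances. No
#' distribution-specific variance (such as the logistic pi^2/3) is added:
#' partitioning stays on the link scale of the fitted model. Set
#' `include_residual = FALSE` to partition among the group terms only.
#'
#' @param draws A `perf_mcmc` fit, or a data frame whose columns are variance
#'   draws (one column per component, a `residual` column included).
#' @param prob Mass of the credible intervals (default 0.95).
#' @param include_residual Include the residual in the denominator (default
#'   `TRUE`, matching how the reference analysis partitions variance).
#' @return A tibble with one row per component: `component`, `share`
#'   (posterior mean), `share_lower`, `share_upper`, and the raw-scale
#'   `variance`, `var_lower`, `var_upper`. The matrix of per-draw shares is
#'   attached as attribute `"share_draws"`.
#' @examples
#' one_draw <- data.frame(host = 2.09, population = 0.046,
#'                        `population:host` = 0.87, culture = 5e-4,
#'                        residual = 1, check.names = FALSE)
#' variance_shares(one_draw)$share[1] # 2.09 / 4.0065
#' @export
variance_shares <- function(draws, prob = 0.95, include_residual = TRUE) {
  vm <- variance_draw_matrix(draws)
  if (!include_residual) vm <- vm[, colnames(vm) != "residual", drop = FALSE]
  if (ncol(vm) < 2) abort("need at least one variance component plus the residual")
  tot <- rowSums(vm)
  if (any(tot <= 0)) abort("zero total variance in at least one draw")
  shares <- vm / tot
  out <- purrr::map_dfr(colnames(vm), function(comp) {
    shpd <- hpd_interval(shares[, comp], prob)
    vhpd <- hpd_interval(vm[, comp], prob)
    tibble::tibble(component = comp,
                   share = mean(shares[, comp]),
                   share_lower = shpd[["lower"]], share_upper = shpd[["upper"]],
                   variance = mean(vm[, comp]),
                   var_lower = vhpd[["lower"]], var_upper = vhpd[["upper"]])
  })
  attr(out, "share_draws") <- shares
  out
}

# variance draws as a plain matrix with component names
variance_draw_matrix <- function(draws) {
  if (inherits(draws, "perf_mcmc")) {
    d <- draws$draws
    cols <- grep("^var_", names(d), value = TRUE)
    vm <- as.matrix(d[cols])
    colnames(vm) <- sub("^var_", "", cols)
  } else if (is.data.frame(draws)) {
    vm <- as.matrix(draws)
  } else {
    abort("`draws` must be a perf_mcmc fit or a data frame of variance draws")
  }
  if (any(vm < 0)) abort("variance draws must be non-negative")
  vm
}

#' Per-draw treatment-level prediction matrix
#'
#' Builds the matrix of posterior prediction draws for each host (level
#' `"host"`) or each population-by-host cell (level `"cell"`), applying the
#' inverse link of the fitted model. Random terms not implied by the
#' requested level (culture, sex, and — for marginal host predictions —
#' population) are set to zero, the conditional-mode convention; for host
#' level, `marginal = "average"` instead averages the inverse-linked cell
#' predictions over populations within each draw.
#'
#' @param fit A `perf_mcmc` object.
#' @param level `"host"` or `"cell"`.
#' @param marginal For `level = "host"`: `"zero"` (default) sets the
#'   population and interaction effects to zero; `"average"` averages over
#'   populations on the response scale.
#' @return A numeric matrix, stored draws by groups; cell columns are named
#'   `"<population>:<host>"`. Attributes `metric`, `level` and `link` are
#'   set.
#' @export
prediction_draws <- function(fit, level = c("host", "cell"),
                             marginal = c("zero", "average")) {
  stopifnot(inherits(fit, "perf_mcmc"))
  level <- match.arg(level)
  marginal <- match.arg(marginal)
  link <- if (fit$spec$family == "binary-logit") "logit" else "identity"
  invlink <- if (link == "logit") plogis else identity
  terms <- names(fit$effects)
  need <- c("host", if (level == "cell" || marginal == "average") c("population", "population:host"))
  missing_terms <- setdiff(need, terms)
  if (length(missing_terms)) {
    abort(sprintf("fit has no draws for term(s): %s", paste(missing_terms, collapse = ", ")))
  }
  mu <- fit$draws$intercept
  uh <- fit$effects[["host"]]
  hosts <- colnames(uh)

  if (level == "host" && marginal == "zero") {
    pred <- invlink(mu + uh)
    colnames(pred) <- hosts
  } else {
    up <- fit$effects[["population"]]
    uph <- fit$effects[["population:host"]]
    pops <- colnames(up)
    cells <- as.vector(outer(pops, hosts, paste, sep = ":"))
    pred <- matrix(NA_real_, nrow = length(mu), ncol = length(cells),
                   dimnames = list(NULL, cells))
    for (p in pops) for (h in hosts) {
      cell <- paste(p, h, sep = ":")
      inter <- if (cell %in% colnames(uph)) uph[, cell] else 0
      pred[, cell] <- invlink(mu + up[, p] + uh[, h] + inter)
    }
    if (level == "host") {
      pred <- vapply(hosts, function(h) {
        rowMeans(pred[, paste(pops, h, sep = ":"), drop = FALSE])
      }, numeric(length(mu)))
    }
  }
  structure(pred, metric = fit$spec$response, level = level, link = link)
}

#' Posterior performance predictions per treatment group
#'
#' Summarises [prediction_draws()] by posterior mean and HPD interval, on the
#' response scale (probabilities for survival, mg for mass, days for
#' development time).
#'
#' @inheritParams prediction_draws
#' @param prob Credible-interval mass.
#' @return A tibble with columns `metric`, `level`, `group` (plus
#'   `population` and `host` for cell level), `mean`, `lower`, `upper`,
#'   `scale`.
#' @export
treatment_predictions <- function(fit, level = c("host", "cell"),
                                  marginal = c("zero", "average"),
                                  prob = 0.95) {
  level <- match.arg(level)
  pred <- prediction_draws(fit, level, marginal)
  out <- purrr::map_dfr(colnames(pred), function(g) {
    ci <- hpd_interval(pred[, g], prob)
    tibble::tibble(metric = attr(pred, "metric"), level = level, group = g,
                   mean = mean(pred[, g]),
                   lower = ci[["lower"]], upper = ci[["upper"]],
                   scale = "response")
  })
  if (level == "cell") {
    parts <- strsplit(out$group, ":", fixed = TRUE)
    out$population <- vapply(parts, `[`, "", 1)
    out$host <- vapply(parts, `[`, "", 2)
  }
  out
}

#' Posterior summary table for a fitted model
#'
#' One row per fixed term and variance component, with the posterior mean,
#' 95% HPD interval and effective sample size — the shape of a
#' variance-component results table.
#'
#' @param fit A `perf_mcmc` object.
#' @param prob Credible-interval mass.
#' @return A tibble with columns `term`, `type`, `mean`, `lower`, `upper`,
#'   `ess`.
#' @export
summarize_model <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "perf_mcmc"))
  d <- fit$draws
  summ <- function(x, term, type) {
    ci <- hpd_interval(x, prob)
    ess <- if (sd(x) == 0) length(x) else
      suppressWarnings(effective_sample_size(x))
    tibble::tibble(term = term, type = type, mean = mean(x),
                   lower = ci[["lower"]], upper = ci[["upper"]],
                   ess = as.numeric(ess))
  }
  rows <- list(summ(d$intercept, "intercept", "fixed"))
  for (col in grep("^var_", names(d), value = TRUE)) {
    term <- sub("^var_", "", col)
    if (term == "residual" && fit$spec$family == "binary-logit") {
      rows <- c(rows, list(tibble::tibble(term = "residual", type = "variance",
                                          mean = d[[col]][1], lower = d[[col]][1],
                                          upper = d[[col]][1], ess = NA_real_)))
    } else {
      rows <- c(rows, list(summ(d[[col]], term, "variance")))
    }
  }
  dplyr::bind_rows(rows)
}

#' @rdname summarize_model
#' @param x A `perf_mcmc` object.
#' @param ... Unused.
#' @export
tidy.perf_mcmc <- function(x, ...) summarize_model(x)

#' One-line fit summary
#'
#' @param x A `perf_mcmc` object.
#' @param ... Unused.
#' @return A one-row tibble: response, family, individuals, stored draws,
#'   minimum ESS across reported terms, Metropolis acceptance (binary model).
#' @export
glance.perf_mcmc <- function(x, ...) {
  s <- summarize_model(x)
  tibble::tibble(response = x$spec$response, family = x$spec$family,
                 n = x$data$n, n_draws = nrow(x$draws),
                 min_ess = min(s$ess, na.rm = TRUE),
                 acceptance = x$acceptance)
}
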