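#' Map of locally abundant host plants per population
#'
#' Encodes the habitat descriptions of the four collection sites into the
#' sets of assayed host plants that are locally abundant: Devon (ancient oak
#' woodland) -> oak; Edinburgh (mature oaks, sycamore abundant) -> oak,
#' sycamore; Buckinghamshire (garden orchard with hawthorn hedges) -> apple,
#' cherry, hawthorn; Suffolk (mixed oak/birch/sycamore woodland) -> oak,
#' birch, sycamore. This encoding is an interpretation of prose habitat
#' descriptions, shipped as a convenient default — supply your own map when
#' the interpretation matters.
#'
#' @return A named list of character vectors (population -> local hosts).
#' @export
default_flora_map <- function() {
  list(Buckinghamshire = c("apple", "cherry", "hawthorn"),
       Devon = "oak",
       Edinburgh = c("oak", "sycamore"),
       Suffolk = c("oak", "birch", "sycamore"))
}

# cell draw matrix must have "<population>:<host>" columns
cell_draw_info <- function(cell_draws) {
  if (inherits(cell_draws, "derived_posterior")) {
    m <- cell_draws$draws
    m <- m[, colnames(m) != "overall", drop = FALSE]
  } else {
    m <- as.matrix(cell_draws)
  }
  parts <- strsplit(colnames(m), ":", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    abort("cell draw columns must be named '<population>:<host>'")
  }
  list(draws = m,
       population = vapply(parts, `[`, "", 1),
       host = vapply(parts, `[`, "", 2))
}

check_flora <- function(flora_map, pops, hosts) {
  missing_pop <- setdiff(pops, names(flora_map))
  if (length(missing_pop)) {
    abort(sprintf("flora map lacks population(s): %s",
                  paste(missing_pop, collapse = ", ")))
  }
  invisible(lapply(flora_map, intersect, hosts))
}

#' Local-vs-foreign criterion
#'
#' First local-adaptation criterion: a local genotype performs better than
#' any other genotype in its local environment. For each host (the
#' "environment" in this common garden), the draw-wise best population is
#' recorded and its frequency across draws is the posterior probability of
#' being best on that host. A host's `local_wins` flag is set when a
#' population for which that host is locally abundant has the highest such
#' probability. Comparisons are rank-based, so the result is invariant to
#' monotone transformations of the performance metric.
#'
#' @param cell_draws Matrix of prediction or derived-metric draws with
#'   `"<population>:<host>"` columns (see [prediction_draws()]), or a
#'   `derived_posterior`.
#' @param flora_map Named list population -> locally abundant hosts; default
#'   [default_flora_map()].
#' @param metric Label recorded in the output.
#' @return A tibble with one row per host by population: `p_best` (posterior
#'   probability that the population is best on that host), `is_local`, and
#'   per host `local_wins` (NA for hosts local to no population, which are
#'   reported rather than dropped).
#' @export
local_vs_foreign <- function(cell_draws, flora_map = default_flora_map(),
                             metric = "fitness") {
  info <- cell_draw_info(cell_draws)
  pops <- sort(unique(info$population))
  hosts <- sort(unique(info$host))
  flora <- check_flora(flora_map, pops, hosts)

  purrr::map_dfr(hosts, function(h) {
    cols <- paste(pops, h, sep = ":")
    sub <- info$draws[, cols, drop = FALSE]
    best <- pops[max.col(sub, ties.method = "first")]
    p_best <- vapply(pops, function(p) mean(best == p), numeric(1))
    is_local <- vapply(pops, function(p) h %in% flora[[p]], logical(1))
    wins <- if (!any(is_local)) NA else
      max(p_best[is_local]) >= max(p_best)
    tibble::tibble(metric = metric, host = h, population = pops,
                   p_best = unname(p_best), is_local = unname(is_local),
                   local_wins = wins)
  })
}

#' Home-vs-away criterion
#'
#' Second local-adaptation criterion: a local genotype performs better in
#' its local environment than in foreign environments. For each population,
#' the draw-wise mean prediction over its home hosts is compared with the
#' mean over away hosts; the reported probability is the posterior mass on
#' home exceeding away. This criterion is known to mislead when environments
#' differ strongly in average quality, so the output carries a caveat flag
#' and should not be read as a definitive test.
#'
#' @inheritParams local_vs_foreign
#' @return A tibble with one row per population: `n_home`, `n_away`,
#'   `p_home_gt_away`, `caveat`.
#' @export
home_vs_away <- function(cell_draws, flora_map = default_flora_map(),
                         metric = "fitness") {
  info <- cell_draw_info(cell_draws)
  pops <- sort(unique(info$population))
  hosts <- sort(unique(info$host))
  flora <- check_flora(flora_map, pops, hosts)

  purrr::map_dfr(pops, function(p) {
    home <- intersect(flora[[p]], hosts)
    if (length(home) == 0) {
      abort(sprintf("population '%s' has no home host among the assayed hosts", p))
    }
    away <- setdiff(hosts, home)
    if (length(away) == 0) {
      abort(sprintf("population '%s' has no away host (all hosts are local)", p))
    }
    hm <- rowMeans(info$draws[, paste(p, home, sep = ":"), drop = FALSE])
    aw <- rowMeans(info$draws[, paste(p, away, sep = ":"), drop = FALSE])
    tibble::tibble(metric = metric, population = p,
                   n_home = length(home), n_away = length(away),
                   p_home_gt_away = mean(hm > aw),
                   caveat = "not a definitive test when environments differ in average quality")
  })
}

#' Combined local-adaptation report
#'
#' Evaluates both criteria on one set of cell-level draws.
#'
#' @inheritParams local_vs_foreign
#' @return A list with elements `local_vs_foreign` and `home_vs_away`.
#' @export
local_adaptation_report <- function(cell_draws,
                                    flora_map = default_flora_map(),
                                    metric = "fitness") {
  list(local_vs_foreign = local_vs_foreign(cell_draws, flora_map, metric),
       home_vs_away = home_vs_away(cell_draws, flora_map, metric))
}
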