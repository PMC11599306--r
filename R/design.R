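#' Define the layout of a rearing assay
#'
#' An assay design crosses source populations with host-plant treatments.
#' Within each population-by-host cell, larvae are reared in cultures of fixed
#' size. The default reproduces the reference layout: 4 populations x 9 hosts
#' x 5 cultures of 20 larvae, i.e. 100 larvae per cell and 3600 in total, with
#' brood pools of 15, 14, 126 and 19 wild-caught females per population.
#'
#' @param n_pops Number of source populations.
#' @param n_hosts Number of host-plant treatments.
#' @param n_cultures_per_cell Rearing cultures per population-by-host cell.
#' @param n_per_culture Larvae per culture.
#' @param broods_per_pop Integer vector, one entry per population: the number
#'   of broods (wild-caught females) in that population's pool.
#' @param populations,hosts Optional label vectors. Defaults use the reference
#'   site and host-plant names when the dimensions match, otherwise
#'   `pop1, pop2, ...` and `host1, host2, ...`.
#' @return An object of class `assay_design`.
#' @examples
#' d <- assay_design()
#' d$n_individuals # 3600
#' @export
assay_design <- function(n_pops = 4, n_hosts = 9, n_cultures_per_cell = 5,
                         n_per_culture = 20,
                         broods_per_pop = if (n_pops == 4) unname(default_broods) else rep(10, n_pops),
                         populations = NULL, hosts = NULL) {
  counts <- c(n_pops = n_pops, n_hosts = n_hosts,
              n_cultures_per_cell = n_cultures_per_cell,
              n_per_culture = n_per_culture)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts))) {
    abort("all design counts must be positive integers")
  }
  if (length(broods_per_pop) != n_pops) {
    abort(sprintf("`broods_per_pop` must have length %d (one per population), got %d",
                  n_pops, length(broods_per_pop)))
  }
  if (any(broods_per_pop < 1)) abort("all brood counts must be >= 1")

  populations <- populations %||%
    (if (n_pops == 4) assay_populations else paste0("pop", seq_len(n_pops)))
  hosts <- hosts %||%
    (if (n_hosts == 9) assay_hosts else paste0("host", seq_len(n_hosts)))
  stopifnot(length(populations) == n_pops, length(hosts) == n_hosts)

  structure(list(
    n_pops = as.integer(n_pops), n_hosts = as.integer(n_hosts),
    n_cultures_per_cell = as.integer(n_cultures_per_cell),
    n_per_culture = as.integer(n_per_culture),
    broods_per_pop = as.integer(broods_per_pop),
    populations = populations, hosts = hosts,
    n_cultures = as.integer(n_pops * n_hosts * n_cultures_per_cell),
    n_individuals = as.integer(n_pops * n_hosts * n_cultures_per_cell * n_per_culture)
  ), class = "assay_design")
}

#' @export
print.assay_design <- function(x, ...) {
  cat("<assay_design>\n")
  cat(sprintf("  %d populations x %d hosts x %d cultures of %d larvae\n",
              x$n_pops, x$n_hosts, x$n_cultures_per_cell, x$n_per_culture))
  cat(sprintf("  %d cultures, %d individuals\n", x$n_cultures, x$n_individuals))
  cat(sprintf("  brood pools: %s\n",
              paste(x$populations, x$broods_per_pop, sep = "=", collapse = ", ")))
  invisible(x)
}

# one row per individual: id, population, host, culture
design_layout <- function(design) {
  stopifnot(inherits(design, "assay_design"))
  cells <- tidyr::expand_grid(population = design$populations, host = design$hosts)
  out <- tidyr::expand_grid(cells,
                            culture_rep = seq_len(design$n_cultures_per_cell),
                            slot = seq_len(design$n_per_culture))
  out <- dplyr::mutate(out,
    culture = paste("cul", .data$population, .data$host, .data$culture_rep, sep = "_"),
    id = dplyr::row_number())
  dplyr::select(out, "id", "population", "host", "culture")
}

#' Assign larvae to broods within their source population
#'
#' Each individual in a culture belonging to population *p* receives a brood
#' drawn uniformly at random from *p*'s brood pool. Cultures are mixed-brood:
#' nothing constrains the larvae of a culture to share a brood, mirroring the
#' rearing protocol in which larvae are assigned to treatment groups and then
#' to cultures at random from across broods.
#'
#' @param design An [assay_design()].
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return A tibble with columns `id` and `brood` (labels of the form
#'   `<population>_b<k>`), one row per individual in the design.
#' @export
assign_broods <- function(design, seed) {
  stopifnot(inherits(design, "assay_design"))
  set.seed(as.integer(seed))
  layout <- design_layout(design)
  dplyr::select(draw_broods(layout, design), "id", "brood")
}

# draws broods using the current RNG state (no seeding)
#
# broods_per_culture = NULL reproduces the rearing protocol: every individual
# draws its brood uniformly from the population pool, independently of its
# culture. Under that assignment individuals are exchangeable within a
# population, so brood effects behave as individual-level noise and create no
# among-culture structure. A finite broods_per_culture emulates batch-wise
# handling (each culture stocked from only k broods), which clusters brood
# membership within cultures — the regime in which unmodelled brood variance
# becomes genuine pseudoreplication.
draw_broods <- function(layout, design, broods_per_culture = NULL) {
  pools <- setNames(design$broods_per_pop, design$populations)
  if (is.null(broods_per_culture)) {
    dplyr::mutate(
      dplyr::group_by(layout, .data$population),
      brood = paste0(.data$population[1], "_b",
                     sample.int(pools[[.data$population[1]]],
                                dplyr::n(), replace = TRUE))
    ) |> dplyr::ungroup()
  } else {
    k <- as.integer(broods_per_culture)
    if (k < 1 || any(k > design$broods_per_pop)) {
      abort("broods_per_culture must be >= 1 and no larger than any population's brood pool")
    }
    dplyr::mutate(
      dplyr::group_by(layout, .data$culture),
      brood = {
        pool <- pools[[.data$population[1]]]
        chosen <- sample.int(pool, k)
        paste0(.data$population[1], "_b",
               chosen[sample.int(k, dplyr::n(), replace = TRUE)])
      }
    ) |> dplyr::ungroup()
  }
}
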