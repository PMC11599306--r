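#' Read and validate an assay table
#'
#' Reads a CSV (or XLSX, when the `readxl` package is available) of
#' individual rearing records and validates it against the assay schema.
#' Required columns: `population`, `host`, `culture`, `survived`; optional:
#' `id`, `brood`, `sex`, `pupal_mass_mg`, `dev_time_days`. Deposited files
#' with different headers can be mapped with `aliases` without touching the
#' file.
#'
#' Validation is two-tier: structural problems (missing required columns,
#' survival values outside {0, 1}) are hard errors naming the offending rows;
#' soft inconsistencies are flagged in a validation report and repaired
#' conservatively — a survivor with a missing mass stays in the table (it
#' still informs the survival model, and the mass model drops it), while a
#' non-survivor carrying a mass or development time has those fields
#' blanked.
#'
#' @param path Path to a `.csv` or `.xlsx` file.
#' @param aliases Optional named character vector mapping standard column
#'   names to the file's headers, e.g. `c(population = "Site")`.
#' @return A tibble of validated records with a `"validation"` attribute:
#'   a tibble of row-level flags (`row`, `issue`).
#' @export
read_assay_table <- function(path, aliases = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("reading XLSX requires the 'readxl' package; convert to CSV")
    }
    tibble::as_tibble(readxl::read_excel(path))
  } else {
    abort(sprintf("unsupported extension '%s' (use .csv or .xlsx)", ext))
  }
  if (!is.null(aliases)) {
    for (std in names(aliases)) {
      if (aliases[[std]] %in% names(raw)) {
        names(raw)[names(raw) == aliases[[std]]] <- std
      }
    }
  }
  required <- c("population", "host", "culture", "survived")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  bad_surv <- which(is.na(raw$survived) | !(raw$survived %in% c(0, 1)))
  if (length(bad_surv)) {
    abort(sprintf("non-binary survival value(s) at row(s): %s",
                  paste(head(bad_surv, 10), collapse = ", ")))
  }
  if (!"id" %in% names(raw)) raw$id <- seq_len(nrow(raw))
  for (col in c("pupal_mass_mg", "dev_time_days")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_real_
  }
  if (!"sex" %in% names(raw)) raw$sex <- NA_character_

  flags <- list()
  note <- function(rows, issue) {
    if (length(rows)) flags[[length(flags) + 1]] <<-
        tibble::tibble(row = rows, issue = issue)
  }
  surv <- raw$survived == 1
  note(which(surv & is.na(raw$pupal_mass_mg)),
       "survivor with missing pupal mass (excluded from mass model)")
  note(which(surv & is.na(raw$dev_time_days)),
       "survivor with missing development time (excluded from devtime model)")
  dead_meas <- which(!surv & (!is.na(raw$pupal_mass_mg) | !is.na(raw$dev_time_days)))
  note(dead_meas, "non-survivor with recorded mass/dev time (fields blanked)")
  raw$pupal_mass_mg[!surv] <- NA_real_
  raw$dev_time_days[!surv] <- NA_real_
  note(which(!is.na(raw$pupal_mass_mg) & raw$pupal_mass_mg <= 0),
       "non-positive pupal mass")
  note(which(!is.na(raw$dev_time_days) & raw$dev_time_days <= 0),
       "non-positive development time")
  # a culture must sit in exactly one population-by-host cell
  cul <- dplyr::distinct(raw, .data$culture, .data$population, .data$host)
  dup <- cul$culture[duplicated(cul$culture)]
  if (length(dup)) {
    abort(sprintf("culture(s) mapped to more than one population-by-host cell: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  report <- if (length(flags)) dplyr::bind_rows(flags) else
    tibble::tibble(row = integer(0), issue = character(0))
  out <- raw[, c("id", "population", "host", "culture",
                 intersect("brood", names(raw)), "sex", "survived",
                 "pupal_mass_mg", "dev_time_days")]
  attr(out, "validation") <- report
  out
}

# ---- draw serialization ----------------------------------------------------

#' Serialise or restore fitted draws
#'
#' `write_draws()` writes one CSV of stored draws (intercept, variance
#' components, and group effects as `u_<term>.<level>` columns) and a JSON
#' sidecar of the model, prior and chain metadata under `<prefix>_draws.csv`
#' / `<prefix>_meta.json`. `read_draws()` reconstructs the `perf_mcmc`.
#'
#' @param fit A `perf_mcmc` object.
#' @param prefix Path prefix for the two files.
#' @return `write_draws()` returns the prefix invisibly; `read_draws()`
#'   returns a `perf_mcmc`.
#' @export
write_draws <- function(fit, prefix) {
  stopifnot(inherits(fit, "perf_mcmc"))
  wide <- fit$draws
  for (term in names(fit$effects)) {
    eff <- fit$effects[[term]]
    colnames(eff) <- paste0("u_", term, ".", colnames(eff))
    wide <- dplyr::bind_cols(wide, tibble::as_tibble(eff))
  }
  readr::write_csv(wide, paste0(prefix, "_draws.csv"))
  meta <- list(spec = fit$spec[c("response", "family", "response_col", "random_terms")],
               priors = unclass(fit$priors),
               settings = unclass(fit$settings),
               data = list(n = fit$data$n, response_mean = fit$data$response_mean,
                           levels = fit$data$levels),
               acceptance = fit$acceptance)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_draws
#' @export
read_draws <- function(prefix) {
  wide <- readr::read_csv(paste0(prefix, "_draws.csv"),
                          show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  spec <- structure(c(meta$spec, list()), class = "model_spec")
  effects <- list()
  for (term in spec$random_terms) {
    cols <- grep(paste0("^u_", gsub("([:.])", "\\\\\\1", term), "\\."),
                 names(wide), value = TRUE)
    eff <- as.matrix(wide[cols])
    colnames(eff) <- substring(cols, nchar(paste0("u_", term, ".")) + 1)
    effects[[term]] <- eff
  }
  draws <- wide[, !grepl("^u_", names(wide))]
  structure(list(draws = draws, effects = effects, spec = spec,
                 priors = do.call(prior_spec, as.list(meta$priors)),
                 settings = do.call(mcmc_settings,
                                    as.list(meta$settings[c("iterations", "burnin", "thin", "seed")])),
                 data = meta$data,
                 acceptance = meta$acceptance %||% NA_real_),
            class = "perf_mcmc")
}

# ---- end-to-end pipeline ---------------------------------------------------

#' Run the full analysis pipeline
#'
#' Orchestrates the stages of the analysis into one reproducible run:
#' simulate (or load) an assay table, fit the three performance models,
#' partition variance, predict per-treatment performance, derive development
#' rate and projected fitness, and evaluate the local-adaptation criteria.
#' All stage outputs are written as CSV under `out_dir`, together with a
#' `provenance.json` recording seeds, chain settings and package version;
#' identical config and seed reproduce every output byte.
#'
#' @param config A named list (or path to a JSON/YAML file) with fields:
#'   `out_dir` (required); `seed` (default 1); `stages` (subset of
#'   `simulate`, `fit`, `partition`, `predict`, `derive`, `local_adapt`;
#'   default all); `data` (path to a CSV, replacing the simulate stage);
#'   `design` (an [assay_design()]); `params` (a [generative_params()] or
#'   config path); `settings` (an [mcmc_settings()]); `fitness` (a
#'   [fitness_config()]); `flora` (named list for the local-adaptation
#'   stage).
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list of in-memory stage outputs plus `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$out_dir)) abort("config$out_dir is required")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  all_stages <- c("simulate", "fit", "partition", "predict", "derive", "local_adapt")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  say <- function(...) if (!quiet) message(sprintf(...))
  res <- list(out_dir = out_dir)

  stage <- "input"
  on_fail <- function(e) {
    abort(sprintf("pipeline failed in stage '%s': %s", stage, conditionMessage(e)))
  }
  tryCatch({
    params <- config$params %||% generative_params()
    if (is.character(params)) params <- params_from_file(params)
    if (!is.null(config$data)) {
      stage <- "load"
      say("loading assay table from %s", config$data)
      dat <- read_assay_table(config$data, aliases = config$aliases)
    } else if ("simulate" %in% stages) {
      stage <- "simulate"
      design <- config$design %||% assay_design()
      say("simulating assay (%d individuals), seed %d", design$n_individuals, seed)
      dat <- simulate_assay(design, params, seed = seed)
      write_assay_csv(dat, file.path(out_dir, "assay_data.csv"))
    } else {
      abort("config must provide `data` or include the 'simulate' stage")
    }
    res$data <- dat

    if ("fit" %in% stages) {
      stage <- "fit"
      settings <- config$settings %||% mcmc_settings(60000, 20000, 40, seed = seed)
      fits <- list()
      for (resp in c("surv", "mass", "devtime")) {
        say("fitting %s model (%d iterations)", resp, settings$iterations)
        st <- settings; st$seed <- seed + match(resp, c("surv", "mass", "devtime"))
        fits[[resp]] <- fit_performance_model(dat, resp, settings = st)
        write_draws(fits[[resp]], file.path(out_dir, resp))
      }
      res$fits <- fits

      if ("partition" %in% stages) {
        stage <- "partition"
        say("partitioning variance")
        res$shares <- purrr::imap_dfr(fits, function(f, resp) {
          dplyr::mutate(variance_shares(f), response = resp, .before = 1)
        })
        readr::write_csv(res$shares, file.path(out_dir, "variance_shares.csv"))
        res$summaries <- purrr::imap_dfr(fits, function(f, resp) {
          dplyr::mutate(summarize_model(f), response = resp, .before = 1)
        })
        readr::write_csv(res$summaries, file.path(out_dir, "model_summaries.csv"))
      }
      if ("predict" %in% stages || "derive" %in% stages || "local_adapt" %in% stages) {
        stage <- "predict"
        say("computing treatment predictions")
        res$predictions <- purrr::map_dfr(c("host", "cell"), function(lv) {
          purrr::imap_dfr(fits, function(f, resp) treatment_predictions(f, lv))
        })
        readr::write_csv(res$predictions, file.path(out_dir, "predictions.csv"))
      }
      if ("derive" %in% stages || "local_adapt" %in% stages) {
        stage <- "derive"
        say("deriving development rate and projected fitness")
        fitness_cfg <- config$fitness %||% params$fitness
        pd <- lapply(fits, prediction_draws, level = "cell")
        pd <- do.call(align_prediction_draws, pd)
        res$rate <- development_rate(pd$mass, pd$devtime,
                                     on_nonpositive = "drop")
        res$fitness <- projected_fitness(pd$surv, pd$mass, fitness_cfg)
        derived <- dplyr::bind_rows(res$rate$summary, res$fitness$summary)
        if ("derive" %in% stages) {
          readr::write_csv(derived, file.path(out_dir, "derived_metrics.csv"))
        }
      }
      if ("local_adapt" %in% stages) {
        stage <- "local_adapt"
        say("evaluating local-adaptation criteria")
        flora <- config$flora %||% default_flora_map()
        rep_ <- local_adaptation_report(res$fitness, flora)
        res$local_adaptation <- rep_
        readr::write_csv(rep_$local_vs_foreign,
                         file.path(out_dir, "local_vs_foreign.csv"))
        readr::write_csv(rep_$home_vs_away,
                         file.path(out_dir, "home_vs_away.csv"))
      }
    }
  }, error = on_fail)

  stage <- "provenance"
  prov <- list(package = "hostassay",
               version = as.character(utils::packageVersion("hostassay")),
               seed = seed, stages = stages,
               settings = if (!is.null(res$fits)) unclass(res$fits[[1]]$settings),
               n_individuals = nrow(res$data))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Deterministic small datasets for examples and tests
#'
#' Builds a bundle of tiny assay tables: `small` (2 populations x 3 hosts x
#' 2 cultures of 10 larvae = 120 rows at moderate parameter values),
#' `zero_variance` (all variance components zero — every individual shares
#' the transformed intercept), and `strong_host` (a dominant host variance).
#' All are deterministic given the seed.
#'
#' @param seed Integer seed.
#' @return A named list of tibbles, plus the shared `design`.
#' @export
make_fixtures <- function(seed = 1) {
  design <- assay_design(2, 3, 2, 10, broods_per_pop = c(5, 5))
  base <- generative_params(
    survival = list(v_pop = 0.05, v_host = 0.5, v_pop_host = 0.1,
                    v_culture = 0.01),
    mass = list(v_pop = 0.5, v_host = 4, v_pop_host = 1, v_culture = 0.05,
                v_resid = 4),
    devtime = list(v_pop = 2, v_host = 4, v_pop_host = 1, v_culture = 0.05,
                   v_resid = 4))
  zero <- generative_params(
    survival = list(v_pop = 0, v_host = 0, v_pop_host = 0, v_culture = 0),
    mass = list(v_pop = 0, v_host = 0, v_pop_host = 0, v_culture = 0,
                v_resid = 1, sex_effect = 0),
    devtime = list(v_pop = 0, v_host = 0, v_pop_host = 0, v_culture = 0,
                   v_resid = 1))
  strong <- generative_params(
    survival = list(v_host = 4, v_pop = 0.01, v_pop_host = 0.01,
                    v_culture = 0.001))
  list(design = design,
       small = simulate_assay(design, base, seed = seed),
       zero_variance = simulate_assay(design, zero, seed = seed + 1),
       strong_host = simulate_assay(design, strong, seed = seed + 2))
}
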