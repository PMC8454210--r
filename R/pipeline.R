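## required columns of the two input tables (UTF-8 CSV, '.' decimal,
## header row mandatory)
sites_schema <- c("site_id", "elevation_m", "latitude_deg", "tg", "tdj",
                  "d0", "r0", "lai", "f", "alpha_p")
traits_schema <- c("site_id", "species", "growth_form", "leaf_habit",
                   "n_fixer", "ma", "narea", "vcmax25")

validate_schema <- function(data, required, file, extra_checks = NULL) {
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort(paste0("`", file, "` is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.null(extra_checks)) extra_checks(data, file)
  invisible(data)
}

check_sites_values <- function(data, file) {
  checks <- list(
    f = function(v) all(v > 0 & v <= 1),
    d0 = function(v) all(v > 0),
    alpha_p = function(v) all(v >= 0),
    lai = function(v) all(v >= 0)
  )
  for (col in names(checks)) {
    bad <- which(!checks[[col]](data[[col]]))
    if (length(bad)) {
      abort(paste0("`", file, "`: column `", col,
                   "` out of range at row(s) ",
                   paste(utils::head(bad, 5), collapse = ", "), "."))
    }
  }
}

#' Read and validate a site table
#'
#' Reads a UTF-8 comma-separated site table, checks the required columns
#' (`site_id`, `elevation_m`, `latitude_deg`, `tg`, `tdj`, `d0`, `r0`,
#' `lai`, `f`, `alpha_p`) and value ranges, and derives the
#' pressure-dependent columns.
#'
#' @param path Path to the CSV file.
#' @param constants A [leaf_constants()] list.
#' @return A validated site tibble with `patm`, `ca` and `r_lai` derived.
#' @export
read_sites <- function(path, constants = leaf_constants()) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  validate_schema(data, sites_schema, basename(path), check_sites_values)
  derive_bioclim(data, as_constants(constants))
}

#' Read and validate a species-level trait table
#'
#' @param path Path to the CSV file.
#' @return A validated trait tibble.
#' @export
read_traits <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  validate_schema(data, traits_schema, basename(path))
  if (is.character(data$n_fixer)) {
    data$n_fixer <- as.logical(data$n_fixer)
  }
  data
}

#' Read a pipeline configuration file
#'
#' YAML configuration with sections `paths` (optional `sites`, `traits`),
#' `constants` (overrides for [leaf_constants()]), `temperature_basis`
#' (per-trait `"tg"`/`"tdj"`), `scenario` (overrides for
#' [transect_scenario()], used when no site table is supplied),
#' `uncertainties` (as in [site_uncertainty()]) and `seed`. Unknown
#' top-level keys are rejected.
#'
#' @param path Path to the YAML file.
#' @return A named list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  known <- c("paths", "constants", "temperature_basis", "scenario",
             "uncertainties", "seed")
  bad <- setdiff(names(config), known)
  if (length(bad)) {
    abort(paste0("Unknown configuration key(s): ",
                 paste(bad, collapse = ", ")))
  }
  structure(config, class = "run_config")
}

#' Run the full trait-prediction pipeline
#'
#' Orchestrates every stage against one site table: (optionally) simulate
#' a synthetic transect, derive bioclimate, predict the four traits,
#' decompose the between-site differences into driver contributions,
#' propagate parameter uncertainty, and evaluate predictions against the
#' (observed or synthetic) trait table. All outputs are written as CSV
#' into `out_dir` together with a JSON provenance record carrying the seed
#' and a hash of the effective configuration.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A list or `"run_config"` as from [read_run_config()];
#'   `NULL` runs the default synthetic scenario.
#' @param seed Integer seed; overrides `config$seed`.
#' @return Invisibly, a named list of the output tibbles (`sites`,
#'   `traits`, `predictions`, `contributions`, `uncertainty`,
#'   `evaluation`).
#' @examples
#' out <- run_pipeline(tempfile("run"), seed = 1)
#' names(out)
#' @export
run_pipeline <- function(out_dir, config = NULL, seed = NULL) {
  config <- config %||% list()
  seed <- seed %||% config$seed %||% 1L
  cst <- do.call(leaf_constants, config$constants %||% list())
  basis <- c(chi = "tdj", vcmax25 = "tdj", ma = "tg")
  if (!is.null(config$temperature_basis)) {
    tb <- unlist(config$temperature_basis)
    basis[names(tb)] <- tb
  }

  if (!is.null(config$paths$sites)) {
    sites <- read_sites(config$paths$sites, cst)
    traits <- if (!is.null(config$paths$traits)) {
      read_traits(config$paths$traits)
    }
    scenario <- NULL
  } else {
    scenario_args <- config$scenario %||% list()
    scenario_args$seed <- seed
    scenario <- do.call(transect_scenario, scenario_args)
    sites <- generate_sites(scenario, cst)
    traits <- generate_traits(sites, scenario, cst, basis)
  }

  predictions <- predict_traits(sites, cst, basis)
  contributions <- decompose_contributions(sites, constants = cst,
                                           temperature_basis = basis)
  unc_spec <- config$uncertainties %||% default_uncertainties()
  uncertainty <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    dplyr::select(
      site_uncertainty(sites[i, ], unc_spec, cst, basis), -"budget")
  })

  evaluation <- NULL
  if (!is.null(traits)) {
    observed <- site_mean_traits(traits)
    joined <- dplyr::left_join(observed, predictions, by = "site_id",
                               suffix = c("_obs", "_pred"))
    evaluation <- purrr::map_dfr(
      intersect(c("chi", "vcmax25", "ma", "narea"), names(observed)),
      function(trait) {
        stats <- agreement_stats(joined, paste0(trait, "_obs"),
                                 paste0(trait, "_pred"))
        dplyr::bind_cols(tibble(trait = trait), stats)
      })
    bench_data <- dplyr::left_join(observed, sites, by = "site_id")
    bench <- benchmark_regression(bench_data)
    evaluation <- dplyr::left_join(
      evaluation,
      dplyr::select(bench, "trait", benchmark_r_squared = "r_squared"),
      by = "trait")
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list(sites = sites, traits = traits,
                  predictions = predictions,
                  contributions = contributions,
                  uncertainty = uncertainty,
                  evaluation = evaluation)
  outputs <- outputs[!vapply(outputs, is.null, logical(1))]
  for (name in names(outputs)) {
    readr::write_csv(outputs[[name]],
                     file.path(out_dir, paste0(name, ".csv")))
  }
  provenance <- list(
    seed = seed,
    config_hash = rlang::hash(list(config = config, seed = seed)),
    temperature_basis = as.list(basis),
    n_sites = nrow(sites),
    outputs = names(outputs)
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outputs)
}
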