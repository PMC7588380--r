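#' Read and validate an exposure grid CSV
#'
#' Expected columns: `country_code`, `cell_id`, `pm25`, `population`, with
#' optional `lon`/`lat` (degrees). UTF-8, header row required.
#'
#' @param path Path to the CSV file.
#' @param quiet Suppress the per-file row/country log line.
#' @return Validated exposure grid tibble.
#' @export
read_exposure_grid <- function(path, quiet = FALSE) {
  g <- read_checked(path, c("country_code", "cell_id", "pm25", "population"),
                    validate_exposure_grid)
  if (!quiet) {
    message(sprintf("read %d cells for %d countries from %s",
                    nrow(g), length(unique(g$country_code)), path))
  }
  g
}

#' Read and validate a baseline mortality CSV
#'
#' Expected columns: `country_code`, `cause`, `sex`, `age_group`, `deaths`.
#' @inheritParams read_exposure_grid
#' @return Validated mortality tibble.
#' @export
read_mortality_table <- function(path, quiet = FALSE) {
  m <- read_checked(path, c("country_code", "cause", "sex", "age_group", "deaths"),
                    validate_mortality)
  if (!quiet) {
    message(sprintf("read %d mortality strata for %d countries from %s",
                    nrow(m), length(unique(m$country_code)), path))
  }
  m
}

#' Read a country population CSV (`country_code`, `population`)
#' @inheritParams read_exposure_grid
#' @return Tibble with country populations.
#' @export
read_population <- function(path, quiet = FALSE) {
  read_checked(path, c("country_code", "population"), function(x) {
    if (any(!is.finite(x$population)) || any(x$population <= 0)) {
      rlang::abort("column `population` must be finite and > 0")
    }
    if (anyDuplicated(x$country_code)) rlang::abort("duplicated country_code")
    invisible(x)
  })
}

#' Read a WHO region membership CSV (`country_code`, `who_region`)
#' @inheritParams read_exposure_grid
#' @return Validated region map tibble.
#' @export
read_region_map <- function(path, quiet = FALSE) {
  read_checked(path, c("country_code", "who_region"), validate_region_map)
}

#' Read a risk-curve parameter draw CSV
#'
#' IER columns: `cause`, `age_group`, `draw_id`, `alpha`, `gamma`, `delta`,
#' `z_cf`. GEMM columns: `cause`, `age_group`, `draw_id`, `theta`,
#' `knot_alpha`, `mu`, `nu`, `z_cf` (an `se_theta` column is carried
#' through if present).
#'
#' @inheritParams read_exposure_grid
#' @param model `"ier"` or `"gemm"`.
#' @return Validated curve draw tibble.
#' @export
read_curves <- function(path, model = c("ier", "gemm"), quiet = FALSE) {
  model <- match.arg(model)
  read_checked(path, curve_cols[[model]], function(x) validate_curves(x, model))
}

#' Read a per-country summary exposure table (XLSX or CSV)
#'
#' Thin import shim for summary-level comparisons against published
#' per-country tables: two columns, `country_code` and `pw_mean`
#' (population-weighted annual-mean PM2.5, ug/m3). `.xlsx` files are read
#' with readxl when installed; any other extension is read as CSV.
#'
#' @param path Path to the file.
#' @return Tibble with `country_code`, `pw_mean`.
#' @export
read_country_summary <- function(path) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      rlang::abort("reading .xlsx requires the readxl package; supply a CSV instead")
    }
    x <- tibble::as_tibble(readxl::read_excel(path))
  } else {
    x <- readr::read_csv(path, show_col_types = FALSE)
  }
  miss <- setdiff(c("country_code", "pw_mean"), names(x))
  if (length(miss)) {
    rlang::abort(sprintf("%s: missing column(s): %s", path, toString(miss)))
  }
  x[, c("country_code", "pw_mean")]
}

read_checked <- function(path, cols, validator) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(cols, names(x))
  if (length(miss)) {
    rlang::abort(sprintf("%s: missing column(s): %s", path, toString(miss)))
  }
  withCallingHandlers(
    validator(x),
    error = function(e) rlang::abort(sprintf("%s: %s", path, conditionMessage(e)))
  )
  tibble::as_tibble(x)
}

#' Write pipeline input tables as CSV
#'
#' Writers matching the dialect the readers consume (round-trip tested):
#' one file per table of a generated or assembled world.
#'
#' @param world List with elements `exposure`, `mortality`, `population`,
#'   `region_map`, `curves` (as returned by [generate_world()]).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    exposure   = file.path(dir, "exposure_grid.csv"),
    mortality  = file.path(dir, "mortality.csv"),
    population = file.path(dir, "population.csv"),
    region_map = file.path(dir, "region_map.csv"),
    curves     = file.path(dir, "ier_curves.csv"))
  for (nm in names(paths)) readr::write_csv(world[[nm]], paths[[nm]])
  invisible(paths)
}

#' Assemble and cross-validate all model inputs
#'
#' Reads the exposure grid, mortality table, country populations, region
#' map and risk-curve draws named in a configuration, enforcing every type
#' invariant at load and the cross-file consistency rules: every mortality
#' country must have exposures, a region and a population, and every
#' mortality cause must have curve draws.
#'
#' @param config A named list (or path to a YAML file) with entries
#'   `exposure`, `mortality`, `population`, `region_map`, `curves` (file
#'   paths) and optional `risk_model` (default `"ier"`).
#' @param quiet Suppress log lines.
#' @return List with the five validated tables plus `risk_model`.
#' @export
read_inputs <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      rlang::abort("reading a YAML config requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  need <- c("exposure", "mortality", "population", "region_map", "curves")
  miss <- setdiff(need, names(config))
  if (length(miss)) rlang::abort(sprintf("config is missing entries: %s", toString(miss)))
  model <- config$risk_model %||% "ier"
  inputs <- list(
    exposure   = read_exposure_grid(config$exposure, quiet = quiet),
    mortality  = read_mortality_table(config$mortality, quiet = quiet),
    population = read_population(config$population, quiet = quiet),
    region_map = read_region_map(config$region_map, quiet = quiet),
    curves     = read_curves(config$curves, model = model, quiet = quiet),
    risk_model = model)
  m_countries <- unique(inputs$mortality$country_code)
  no_exposure <- setdiff(m_countries, unique(inputs$exposure$country_code))
  if (length(no_exposure)) {
    rlang::abort(sprintf("country present in mortality but absent from exposures: %s",
                         toString(no_exposure)))
  }
  no_region <- setdiff(m_countries, inputs$region_map$country_code)
  if (length(no_region)) {
    rlang::abort(sprintf("country missing from region map: %s", toString(no_region)))
  }
  no_pop <- setdiff(m_countries, inputs$population$country_code)
  if (length(no_pop)) {
    rlang::abort(sprintf("country missing from population table: %s", toString(no_pop)))
  }
  no_curve <- setdiff(unique(inputs$mortality$cause), unique(inputs$curves$cause))
  if (length(no_curve)) {
    rlang::abort(sprintf("no curve draws for cause(s): %s", toString(no_curve)))
  }
  inputs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
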