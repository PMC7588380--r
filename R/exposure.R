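#' WHO interim-target and guideline exposure scenarios
#'
#' The scenario ladder of the 2005 WHO air quality guidelines: current
#' (uncapped) exposure, interim targets IT1 (35), IT2 (25), IT3 (15) and the
#' guideline level AQG (10 ug/m3 annual mean). Caps are applied grid-cell
#' wise by [cap_exposures()].
#'
#' @param names Scenario labels to return, a subset of the default ladder.
#' @return Tibble with columns `name` and `cap` (ug/m3; `NA` for "current").
#' @examples
#' who_scenarios()
#' @export
who_scenarios <- function(names = c("current", "IT1", "IT2", "IT3", "AQG")) {
  ladder <- tibble::tibble(
    name = c("current", "IT1", "IT2", "IT3", "AQG"),
    cap  = c(NA_real_, 35, 25, 15, 10)
  )
  bad <- setdiff(names, ladder$name)
  if (length(bad)) rlang::abort(sprintf("unknown scenario name(s): %s", toString(bad)))
  ladder[match(names, ladder$name), ]
}

#' Validate a gridded exposure table
#'
#' An exposure grid is a tibble with one row per grid cell: `country_code`
#' (ISO3-style label), `cell_id`, `pm25` (annual-mean ug/m3, finite and
#' >= 0) and `population` (persons, >= 0); optional `lon`/`lat`. Every
#' country must have at least one populated cell. Cells with zero
#' population are retained (they contribute nothing to burden) so files
#' round-trip unchanged.
#'
#' @param grid Data frame of grid cells.
#' @return `grid` invisibly if valid, else an error naming the violation.
#' @export
validate_exposure_grid <- function(grid) {
  need <- c("country_code", "cell_id", "pm25", "population")
  miss <- setdiff(need, names(grid))
  if (length(miss)) {
    rlang::abort(sprintf("exposure grid is missing column(s): %s", toString(miss)))
  }
  if (nrow(grid) == 0L) rlang::abort("exposure grid has no cells")
  if (!is.numeric(grid$pm25) || any(!is.finite(grid$pm25))) {
    rlang::abort("exposure grid column `pm25` must be finite numeric")
  }
  if (any(grid$pm25 < 0)) {
    bad <- which(grid$pm25 < 0)[1]
    rlang::abort(sprintf("negative pm25 (%g) in cell `%s`", grid$pm25[bad], grid$cell_id[bad]))
  }
  if (!is.numeric(grid$population) || any(!is.finite(grid$population)) ||
      any(grid$population < 0)) {
    rlang::abort("exposure grid column `population` must be finite and >= 0")
  }
  totals <- tapply(grid$population, grid$country_code, sum)
  if (any(totals <= 0)) {
    rlang::abort(sprintf("country `%s` has no populated cell", names(totals)[totals <= 0][1]))
  }
  invisible(grid)
}

#' Cap grid-cell exposures at a scenario level
#'
#' Replaces each cell's PM2.5 concentration with the scenario cap wherever
#' the current level is higher (`pm25 := min(pm25, cap)`); populations,
#' cell order and all other columns are unchanged. The cap applies to grid
#' cells, not to country means. Capping is idempotent and monotone in the
#' cap.
#'
#' @param grid Exposure grid (see [validate_exposure_grid()]).
#' @param scenario Either a one-row scenario (e.g. a row of
#'   [who_scenarios()]), a scenario name from the default ladder, or a
#'   single non-negative cap in ug/m3. `NA` or `"current"` returns the grid
#'   unchanged.
#' @return The capped exposure grid.
#' @examples
#' g <- tibble::tibble(country_code = "AAA", cell_id = 1:3,
#'                     pm25 = c(5, 20, 40), population = 1)
#' cap_exposures(g, 10)$pm25
#' @export
cap_exposures <- function(grid, scenario) {
  validate_exposure_grid(grid)
  cap <- scenario_cap(scenario)
  if (is.na(cap)) return(grid)
  grid$pm25 <- pmin(grid$pm25, cap)
  grid
}

scenario_cap <- function(scenario) {
  if (is.data.frame(scenario)) {
    if (nrow(scenario) != 1L || is.null(scenario$cap)) {
      rlang::abort("`scenario` data frame must be a single row with a `cap` column")
    }
    scenario <- scenario$cap
  }
  if (is.character(scenario)) {
    scenario <- who_scenarios(scenario)$cap
  }
  if (length(scenario) != 1L || !is.numeric(scenario)) {
    rlang::abort("`scenario` must resolve to a single numeric cap (or NA for current)")
  }
  if (!is.na(scenario) && scenario < 0) {
    rlang::abort(sprintf("scenario cap must be >= 0 ug/m3 (got %g)", scenario))
  }
  as.numeric(scenario)
}

#' Population-weighted mean exposure by country
#'
#' @param grid Exposure grid (see [validate_exposure_grid()]).
#' @return Tibble with `country_code` and `pw_mean`
#'   (sum(pm25 * population) / sum(population), ug/m3), one row per country.
#' @examples
#' g <- tibble::tibble(country_code = "AAA", cell_id = 1:2,
#'                     pm25 = c(10, 20), population = c(1, 3))
#' population_weighted_mean(g)
#' @export
population_weighted_mean <- function(grid) {
  validate_exposure_grid(grid)
  grid |>
    dplyr::group_by(.data$country_code) |>
    dplyr::summarise(
      pw_mean = sum(.data$pm25 * .data$population) / sum(.data$population),
      .groups = "drop"
    )
}

#' Population share living above an exposure threshold
#'
#' Diagnostic echoing the "share of the population living in areas
#' exceeding the guideline" framing: the population-weighted fraction of
#' cells with `pm25` strictly greater than `threshold`.
#'
#' @param grid Exposure grid.
#' @param threshold Concentration threshold, ug/m3.
#' @return Tibble with `country_code` and `fraction` in `[0, 1]`.
#' @export
fraction_above <- function(grid, threshold) {
  validate_exposure_grid(grid)
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold)) {
    rlang::abort("`threshold` must be a single finite number (ug/m3)")
  }
  grid |>
    dplyr::group_by(.data$country_code) |>
    dplyr::summarise(
      fraction = sum(.data$population[.data$pm25 > threshold]) / sum(.data$population),
      .groups = "drop"
    )
}
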