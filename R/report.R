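#' Format a point estimate with its 95% uncertainty interval
#'
#' Follows the "point (low, high)" table convention: percentages as
#' `"47.8% (40.8%, 55.2%)"`, death counts with thousands separators as
#' `"403,371 (328,251-480,618)"`.
#'
#' @param point,low,high Numeric vectors (recycled together).
#' @param unit `"count"` or `"percent"`.
#' @param digits Decimal places (default 0 for counts, 1 for percentages).
#' @return Character vector.
#' @examples
#' format_ui(47.8, 40.8, 55.2, unit = "percent")
#' @export
format_ui <- function(point, low, high, unit = c("count", "percent"),
                      digits = NULL) {
  unit <- match.arg(unit)
  if (is.null(digits)) digits <- if (unit == "percent") 1L else 0L
  if (unit == "percent") {
    out <- sprintf("%.*f%% (%.*f%%, %.*f%%)", digits, point, digits, low, digits, high)
  } else {
    fmt <- function(x) formatC(round(x, digits), format = "f", digits = digits,
                               big.mark = ",")
    out <- sprintf("%s (%s-%s)", fmt(point), fmt(low), fmt(high))
  }
  out[!is.finite(point)] <- NA_character_
  out
}

#' Render the publication-style output tables for a burden run
#'
#' Writes three artefacts to `dir`, every number taken from the run's
#' stored draw vectors (nothing is re-derived at render time):
#' \itemize{
#'   \item `region_scenario_table.csv` — region and world attributable
#'     deaths and percent reductions per scenario, machine-readable
#'     columns plus `"point (low-high)"` formatted companions;
#'   \item `country_rates_per100k.csv` — per-country attributable-death
#'     rates per 100,000 under each scenario and the avoided rate
#'     relative to current exposures;
#'   \item `manifest.json` — seed, draw count, risk model, scenario caps,
#'     counterfactual bounds and a configuration hash, so a run can be
#'     reproduced byte-identically.
#' }
#'
#' @param run A `burden_run`.
#' @param region_map Country-to-WHO-region table.
#' @param population Country population table (`country_code`,
#'   `population`).
#' @param dir Output directory (created if needed).
#' @param quiet Suppress the per-scenario log lines.
#' @return Named character vector of files written, invisibly.
#' @export
render_tables <- function(run, region_map, population, dir, quiet = FALSE) {
  stopifnot(inherits(run, "burden_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  deaths_region <- dplyr::bind_rows(
    burden_estimates(run, "region", region_map),
    burden_estimates(run, "world"))
  has_reduction <- "current" %in% run$scenarios$name && nrow(run$scenarios) > 1L
  if (has_reduction) {
    red_region <- dplyr::bind_rows(
      percent_reduction(run, "region", region_map),
      percent_reduction(run, "world")) |>
      dplyr::rename(reduction_point = "point", reduction_ui_low = "ui_low",
                    reduction_ui_high = "ui_high")
    regional <- dplyr::left_join(deaths_region, red_region, by = c("scenario", "unit"))
  } else {
    regional <- deaths_region
  }
  regional <- regional |>
    dplyr::mutate(deaths_fmt = format_ui(.data$point, .data$ui_low, .data$ui_high))
  if (has_reduction) {
    regional <- regional |>
      dplyr::mutate(reduction_fmt = format_ui(.data$reduction_point,
                                              .data$reduction_ui_low,
                                              .data$reduction_ui_high,
                                              unit = "percent"))
  }
  regional <- regional |>
    dplyr::arrange(match(.data$scenario, run$scenarios$name),
                   .data$unit != "World", .data$unit)

  country_rates <- burden_estimates(run, "country") |>
    deaths_per_100k(population_by_unit(population, "country"))
  if (has_reduction) {
    cur <- country_rates |>
      dplyr::filter(.data$scenario == "current") |>
      dplyr::select("unit", current_rate = "point")
    country_rates <- country_rates |>
      dplyr::left_join(cur, by = "unit") |>
      dplyr::mutate(avoided_per_100k = .data$current_rate - .data$point) |>
      dplyr::select(-"current_rate")
  }
  country_rates <- dplyr::arrange(country_rates,
                                  match(.data$scenario, run$scenarios$name), .data$unit)

  manifest <- list(
    package = "pmburden",
    version = as.character(utils::packageVersion("pmburden")),
    seed = run$seed, n_draws = run$n_draws, risk_model = run$risk_model,
    point_summary = run$point,
    counterfactual = list(low = run$cf$low, high = run$cf$high,
                          distribution = run$cf$distribution),
    scenarios = as.list(stats::setNames(run$scenarios$cap, run$scenarios$name)),
    n_countries = length(unique(run$strata$country_code)),
    n_strata = nrow(run$strata),
    config_hash = rlang::hash(list(run$seed, run$n_draws, run$risk_model, run$point,
                                   run$cf$low, run$cf$high, run$scenarios,
                                   run$strata)))

  paths <- c(regional = file.path(dir, "region_scenario_table.csv"),
             country  = file.path(dir, "country_rates_per100k.csv"),
             manifest = file.path(dir, "manifest.json"))
  readr::write_csv(regional, paths[["regional"]], na = "")
  readr::write_csv(country_rates, paths[["country"]], na = "")
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  if (!quiet) {
    for (i in seq_len(nrow(run$scenarios))) {
      cap <- run$scenarios$cap[i]
      message(sprintf("rendered scenario %s%s for %d units",
                      run$scenarios$name[i],
                      if (is.na(cap)) "" else sprintf(" (cap %g ug/m3)", cap),
                      length(unique(regional$unit))))
    }
  }
  invisible(paths)
}
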