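#' Attributable deaths for one stratum under one fixed parameter draw
#'
#' Deterministic core of the comparative risk assessment: baseline deaths in
#' a country stratum are apportioned to grid cells proportionally to
#' population, and each cell contributes its population attributable
#' fraction at the cell's exposure:
#' \deqn{\sum_i D \frac{pop_i}{\sum_j pop_j} \mathrm{PAF}(RR(z_i))}
#'
#' @param grid Exposure grid for a single country.
#' @param draw A single risk-curve parameter draw (IER fields `alpha`,
#'   `gamma`, `delta`, `z_cf`; or GEMM fields `theta`, `knot_alpha`, `mu`,
#'   `nu`, `z_cf` — the model is detected from the fields present).
#' @param deaths Baseline deaths in the stratum (single count, >= 0).
#' @param cause,age_group Optional stratum labels; if supplied and the draw
#'   carries `cause`/`age_group` fields, a mismatch is rejected.
#' @return Attributable deaths (single number in `[0, deaths)`).
#' @examples
#' g <- tibble::tibble(country_code = "AAA", cell_id = 1:2,
#'                     pm25 = c(4, 30), population = c(500, 500))
#' d <- list(alpha = 1, gamma = 0.1, delta = 1, z_cf = 5)
#' attributable_deaths_one_draw(g, d, deaths = 1000)
#' @export
attributable_deaths_one_draw <- function(grid, draw, deaths,
                                         cause = NULL, age_group = NULL) {
  validate_exposure_grid(grid)
  if (length(unique(grid$country_code)) != 1L) {
    rlang::abort("`grid` must contain a single country")
  }
  if (!is.numeric(deaths) || length(deaths) != 1L || !is.finite(deaths) || deaths < 0) {
    rlang::abort("`deaths` must be a single finite count >= 0")
  }
  draw <- as.list(draw)
  if (!is.null(cause) && !is.null(draw$cause) && !identical(cause, draw$cause)) {
    rlang::abort(sprintf("curve draw is for cause `%s` but stratum is `%s`",
                         draw$cause, cause))
  }
  if (!is.null(age_group) && !is.null(draw$age_group) &&
      !identical(draw$age_group, "all") && !identical(age_group, draw$age_group)) {
    rlang::abort(sprintf("curve draw is for age group `%s` but stratum is `%s`",
                         draw$age_group, age_group))
  }
  rr <- if (!is.null(draw$theta)) evaluate_gemm(grid$pm25, draw) else evaluate_ier(grid$pm25, draw)
  w <- grid$population / sum(grid$population)
  deaths * sum(w * paf(rr))
}

#' Monte-Carlo burden of attributable deaths under exposure scenarios
#'
#' Runs the full comparative risk assessment: for each of `n_draws` matched
#' Monte-Carlo draws, a counterfactual concentration is sampled from `cf`
#' and paired with one parameter draw of every exposure-response curve
#' (draws are cycled in `draw_id` order when the curve table has fewer
#' draws than `n_draws`). Within a draw the same counterfactual and curve
#' parameters are used for the current exposures and for every capped
#' scenario, which is what makes scenario differences well-defined.
#' Attributable deaths are evaluated for every country/cause/sex/age
#' stratum and stored per draw; summaries (point and 95% uncertainty
#' interval) are produced by [burden_estimates()] and [percent_reduction()].
#'
#' Curve/stratum matching: causes with a single curve age band (labelled
#' e.g. `"all"`) apply that curve to every age group of the cause; causes
#' with several bands (typically IHD and stroke) require an exact
#' age-group match.
#'
#' With `risk_model = "gemm"` the counterfactual is fixed per curve draw
#' (the model's own `z_cf` column, anchored at 2.4 ug/m3 in the published
#' fit) and `cf` is ignored.
#'
#' @param grid Exposure grid covering every country in `mortality`.
#' @param mortality Baseline mortality table (see [validate_mortality()]).
#' @param curves Risk-curve parameter draw table (see [validate_curves()]).
#' @param scenarios Scenario table (default [who_scenarios()]); must
#'   include `"current"` for reductions to be defined.
#' @param cf [counterfactual_spec()] for the sampled TMREL.
#' @param n_draws Number of Monte-Carlo draws (>= 1).
#' @param seed Integer seed; identical seeds give identical output.
#' @param point Draw summary used for point estimates: `"mean"` (default)
#'   or `"median"`.
#' @param risk_model `"ier"` (default) or `"gemm"`.
#' @return An object of class `burden_run` holding the per-draw
#'   attributable deaths for every stratum and scenario, plus run metadata.
#' @export
run_monte_carlo <- function(grid, mortality, curves,
                            scenarios = who_scenarios(),
                            cf = counterfactual_spec(),
                            n_draws = 1000L, seed,
                            point = c("mean", "median"),
                            risk_model = c("ier", "gemm")) {
  point <- match.arg(point)
  risk_model <- match.arg(risk_model)
  validate_exposure_grid(grid)
  validate_mortality(mortality)
  validate_curves(curves, risk_model)
  if (!inherits(cf, "counterfactual_spec")) cf <- do.call(counterfactual_spec, as.list(cf))
  if (!is.numeric(n_draws) || length(n_draws) != 1L || n_draws < 1) {
    rlang::abort("`n_draws` must be a single integer >= 1")
  }
  n_draws <- as.integer(n_draws)
  if (missing(seed)) rlang::abort("`seed` is required for a reproducible run")
  missing_exp <- setdiff(unique(mortality$country_code), unique(grid$country_code))
  if (length(missing_exp)) {
    rlang::abort(sprintf("country present in mortality but absent from exposures: %s",
                         toString(missing_exp)))
  }
  strata <- match_curve_strata(mortality, curves)

  set.seed(as.integer(seed))
  z_cf_draws <- stats::runif(n_draws, cf$low, cf$high)

  # one parameter matrix per curve stratum, cycled to n_draws rows
  curve_strata <- curves |>
    dplyr::arrange(.data$cause, .data$age_group, .data$draw_id) |>
    dplyr::group_by(.data$cause, .data$age_group) |>
    dplyr::group_split()
  names(curve_strata) <- vapply(curve_strata, function(d)
    paste(d$cause[1], d$age_group[1], sep = "\r"), character(1))
  cycled <- lapply(curve_strata, function(d) {
    idx <- ((seq_len(n_draws) - 1L) %% nrow(d)) + 1L
    d[idx, , drop = FALSE]
  })

  countries <- split(grid, grid$country_code)
  needed <- dplyr::distinct(strata, .data$country_code, .data$cause, .data$curve_age)

  paf_tbl <- lapply(seq_len(nrow(scenarios)), function(si) {
    scen <- scenarios[si, ]
    out <- lapply(seq_len(nrow(needed)), function(ri) {
      cc <- needed$country_code[ri]
      key <- paste(needed$cause[ri], needed$curve_age[ri], sep = "\r")
      g <- countries[[cc]]
      pm <- if (is.na(scen$cap)) g$pm25 else pmin(g$pm25, scen$cap)
      w <- g$population / sum(g$population)
      par <- cycled[[key]]
      pafbar <- if (risk_model == "ier") {
        pw_paf_ier(pm, w, par$alpha, par$gamma, par$delta, z_cf_draws)
      } else {
        pw_paf_gemm(pm, w, par$theta, par$knot_alpha, par$mu, par$nu, par$z_cf)
      }
      tibble::tibble(scenario = scen$name, country_code = cc,
                     cause = needed$cause[ri], curve_age = needed$curve_age[ri],
                     draw = seq_len(n_draws), paf = pafbar)
    })
    dplyr::bind_rows(out)
  })
  paf_tbl <- dplyr::bind_rows(paf_tbl)

  draws <- strata |>
    dplyr::inner_join(paf_tbl, by = c("country_code", "cause", "curve_age"),
                      relationship = "many-to-many") |>
    dplyr::mutate(attributable = .data$deaths * .data$paf) |>
    dplyr::select("scenario", "country_code", "cause", "sex", "age_group",
                  "draw", "attributable")

  structure(list(
    draws = draws, strata = strata, scenarios = scenarios, cf = cf,
    z_cf = z_cf_draws, n_draws = n_draws, seed = as.integer(seed),
    point = point, risk_model = risk_model
  ), class = "burden_run")
}

#' @export
print.burden_run <- function(x, ...) {
  cat(sprintf(
    "<burden_run> %s model, %d draws (seed %d), %d countries, scenarios: %s\n",
    toupper(x$risk_model), x$n_draws, x$seed,
    length(unique(x$strata$country_code)), toString(x$scenarios$name)))
  invisible(x)
}

# population-weighted PAF per draw; pm: n_cells, parameters: n_draws
pw_paf_ier <- function(pm, w, alpha, gamma, delta, z_cf) {
  n <- length(pm); m <- length(alpha)
  E <- pmax(pm - matrix(z_cf, n, m, byrow = TRUE), 0)
  RR <- 1 + matrix(alpha, n, m, byrow = TRUE) *
    (1 - exp(-matrix(gamma, n, m, byrow = TRUE) * E^matrix(delta, n, m, byrow = TRUE)))
  as.numeric(crossprod(w, (RR - 1) / RR))
}

pw_paf_gemm <- function(pm, w, theta, knot_alpha, mu, nu, z_cf) {
  n <- length(pm); m <- length(theta)
  E <- pmax(pm - matrix(z_cf, n, m, byrow = TRUE), 0)
  W <- 1 / (1 + exp(-(E - matrix(mu, n, m, byrow = TRUE)) / matrix(nu, n, m, byrow = TRUE)))
  HR <- exp(matrix(theta, n, m, byrow = TRUE) *
              log1p(E / matrix(knot_alpha, n, m, byrow = TRUE)) * W)
  as.numeric(crossprod(w, (HR - 1) / HR))
}

# attach the curve age band serving each mortality stratum
match_curve_strata <- function(mortality, curves) {
  by_cause <- tapply(curves$age_group, curves$cause, function(a) sort(unique(a)),
                     simplify = FALSE)
  no_curve <- setdiff(unique(mortality$cause), names(by_cause))
  if (length(no_curve)) {
    rlang::abort(sprintf("no curve draws supplied for cause(s): %s", toString(no_curve)))
  }
  curve_age <- character(nrow(mortality))
  for (cs in unique(mortality$cause)) {
    rows <- mortality$cause == cs
    bands <- by_cause[[cs]]
    if (length(bands) == 1L) {
      curve_age[rows] <- bands
    } else {
      unmatched <- setdiff(unique(mortality$age_group[rows]), bands)
      if (length(unmatched)) {
        rlang::abort(sprintf(
          "cause `%s` has age-specific curves (%s) but mortality age band `%s` has no match",
          cs, toString(bands), unmatched[1]))
      }
      curve_age[rows] <- mortality$age_group[rows]
    }
  }
  dplyr::mutate(tibble::as_tibble(mortality), curve_age = curve_age)
}

#' Per-draw attributable deaths aggregated to countries, regions or world
#'
#' Aggregation is always performed on the per-draw vectors (sum within a
#' draw, then summarise), never on already-summarised intervals, so the
#' world total of any draw equals the sum of its regions and countries
#' exactly.
#'
#' @param run A `burden_run` from [run_monte_carlo()].
#' @param level `"world"`, `"region"` or `"country"`.
#' @param region_map Required for `level = "region"`: table with
#'   `country_code`, `who_region`. Every country in the run must appear.
#' @param by_cause Keep cause-specific totals instead of all-cause.
#' @return Tibble with `scenario`, `unit`, optional `cause`, `draw`,
#'   `deaths`.
#' @export
burden_draws <- function(run, level = c("world", "region", "country"),
                         region_map = NULL, by_cause = FALSE) {
  stopifnot(inherits(run, "burden_run"))
  level <- match.arg(level)
  d <- run$draws
  if (level == "world") {
    d$unit <- "World"
  } else if (level == "country") {
    d$unit <- d$country_code
  } else {
    if (is.null(region_map)) rlang::abort("`region_map` is required for level = \"region\"")
    validate_region_map(region_map)
    unmapped <- setdiff(unique(d$country_code), region_map$country_code)
    if (length(unmapped)) {
      rlang::abort(sprintf("country not in region map: %s", toString(unmapped)))
    }
    d$unit <- region_map$who_region[match(d$country_code, region_map$country_code)]
  }
  keys <- c("scenario", "unit", if (by_cause) "cause", "draw")
  d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(deaths = sum(.data$attributable), .groups = "drop")
}

#' Summarise attributable deaths as point estimates with 95% UIs
#'
#' @inheritParams burden_draws
#' @return Tibble with `scenario`, `unit`, optional `cause`, `point`,
#'   `ui_low`, `ui_high` (2.5th/97.5th percentiles over draws).
#' @export
burden_estimates <- function(run, level = c("world", "region", "country"),
                             region_map = NULL, by_cause = FALSE) {
  level <- match.arg(level)
  keys <- c("scenario", "unit", if (by_cause) "cause")
  burden_draws(run, level, region_map, by_cause) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      point   = summarise_point(.data$deaths, run$point),
      ui_low  = stats::quantile(.data$deaths, 0.025, names = FALSE),
      ui_high = stats::quantile(.data$deaths, 0.975, names = FALSE),
      .groups = "drop"
    )
}

summarise_point <- function(x, point) {
  if (point == "median") stats::median(x) else mean(x)
}

#' Percent reduction in attributable deaths relative to current exposures
#'
#' For each scenario and aggregation unit the reduction is computed per
#' matched draw, \eqn{r_d = 100 (D_{current,d} - D_{scenario,d}) /
#' D_{current,d}}, then summarised as a point estimate and 95% UI. This
#' draw-level summary need not equal the ratio of the summarised death
#' totals. Units with a zero current-level draw are reported as `NA`
#' (undefined), not 0.
#'
#' @inheritParams burden_draws
#' @return Tibble with `scenario` (all non-`current` scenarios, plus
#'   `current` itself at exactly 0), `unit`, optional `cause`, `point`,
#'   `ui_low`, `ui_high`, in percent.
#' @export
percent_reduction <- function(run, level = c("world", "region", "country"),
                              region_map = NULL, by_cause = FALSE) {
  level <- match.arg(level)
  if (!"current" %in% run$scenarios$name) {
    rlang::abort("run has no `current` scenario to compare against")
  }
  d <- burden_draws(run, level, region_map, by_cause)
  keys <- c("unit", if (by_cause) "cause", "draw")
  cur <- d |>
    dplyr::filter(.data$scenario == "current") |>
    dplyr::select(dplyr::all_of(keys), current = "deaths")
  keys_nodraw <- c("scenario", "unit", if (by_cause) "cause")
  d |>
    dplyr::inner_join(cur, by = keys) |>
    dplyr::mutate(reduction = 100 * (.data$current - .data$deaths) / .data$current) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys_nodraw))) |>
    dplyr::summarise(
      point   = if (any(.data$current == 0)) NA_real_ else summarise_point(.data$reduction, run$point),
      ui_low  = if (any(.data$current == 0)) NA_real_ else stats::quantile(.data$reduction, 0.025, names = FALSE),
      ui_high = if (any(.data$current == 0)) NA_real_ else stats::quantile(.data$reduction, 0.975, names = FALSE),
      .groups = "drop"
    )
}

#' Convert death totals to rates per 100,000 people
#'
#' @param estimates A tibble with a `unit` column and numeric `point`,
#'   `ui_low`, `ui_high` columns (as returned by [burden_estimates()]).
#' @param population Either a single population count (applied to every
#'   row) or a tibble with `unit` and `population` covering every unit in
#'   `estimates` (see [population_by_unit()]).
#' @return `estimates` with `point`/`ui_low`/`ui_high` rescaled to deaths
#'   per 100,000 and a `population` column appended.
#' @export
deaths_per_100k <- function(estimates, population) {
  if (is.numeric(population) && length(population) == 1L) {
    population <- tibble::tibble(unit = unique(estimates$unit), population = population)
  }
  if (!all(c("unit", "population") %in% names(population))) {
    rlang::abort("`population` must be a single count or a tibble with `unit` and `population`")
  }
  if (any(!is.finite(population$population)) || any(population$population <= 0)) {
    rlang::abort("populations must be finite and > 0")
  }
  missing_pop <- setdiff(unique(estimates$unit), population$unit)
  if (length(missing_pop)) {
    rlang::abort(sprintf("no population for unit(s): %s", toString(missing_pop)))
  }
  estimates |>
    dplyr::inner_join(population[, c("unit", "population")], by = "unit") |>
    dplyr::mutate(dplyr::across(dplyr::any_of(c("point", "ui_low", "ui_high")),
                                ~ .x * 1e5 / .data$population))
}

#' Aggregate country populations to the units of an estimate table
#'
#' @param population Tibble with `country_code` and `population`.
#' @param level `"world"`, `"region"` or `"country"`.
#' @param region_map Required for `level = "region"`.
#' @return Tibble with `unit` and `population`.
#' @export
population_by_unit <- function(population, level = c("world", "region", "country"),
                               region_map = NULL) {
  level <- match.arg(level)
  if (!all(c("country_code", "population") %in% names(population))) {
    rlang::abort("`population` must have columns country_code and population")
  }
  if (level == "world") {
    return(tibble::tibble(unit = "World", population = sum(population$population)))
  }
  if (level == "country") {
    return(tibble::tibble(unit = population$country_code,
                          population = population$population))
  }
  validate_region_map(region_map)
  unmapped <- setdiff(population$country_code, region_map$country_code)
  if (length(unmapped)) {
    rlang::abort(sprintf("country not in region map: %s", toString(unmapped)))
  }
  population |>
    dplyr::mutate(unit = region_map$who_region[match(.data$country_code,
                                                     region_map$country_code)]) |>
    dplyr::group_by(.data$unit) |>
    dplyr::summarise(population = sum(.data$population), .groups = "drop")
}
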