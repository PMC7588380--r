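# Fixtures are built in code; nothing is read from disk except round-trip
# tests that first write to a temporary directory.

tiny_grid <- function(pm25, population = rep(1, length(pm25)), code = "AAA") {
  tibble::tibble(country_code = code,
                 cell_id = sprintf("%s_%03d", code, seq_along(pm25)),
                 pm25 = pm25, population = population)
}

ier_draw <- function(alpha = 1, gamma = 0.1, delta = 1, z_cf = 5,
                     cause = NULL, age_group = NULL, draw_id = 1L) {
  d <- list(alpha = alpha, gamma = gamma, delta = delta, z_cf = z_cf,
            draw_id = draw_id)
  if (!is.null(cause)) d$cause <- cause
  if (!is.null(age_group)) d$age_group <- age_group
  d
}

# single-country, single-cause world with uniform exposure: the closed-form
# oracle setting (PAF identical in every cell)
flat_world <- function(E = 30, deaths = c(600, 400), n_cells = 4, code = "AAA",
                       alpha = 0.8, gamma = 0.05, delta = 0.9) {
  list(
    grid = tiny_grid(rep(E, n_cells), population = seq_len(n_cells) * 100, code = code),
    mortality = tibble::tibble(country_code = code, cause = "LRI",
                               sex = c("male", "female"), age_group = "all",
                               deaths = deaths),
    curves = tibble::tibble(cause = "LRI", age_group = "all", draw_id = 1L,
                            alpha = alpha, gamma = gamma, delta = delta, z_cf = 3))
}

# minimal burden_run with hand-chosen per-draw deaths, for testing the
# draw-level summaries in isolation
fake_run <- function(per_draw, point = "mean") {
  # per_draw: tibble(scenario, country_code, draw, attributable)
  draws <- per_draw |>
    dplyr::mutate(cause = "LRI", sex = "male", age_group = "all")
  strata <- draws |>
    dplyr::distinct(country_code, cause, sex, age_group) |>
    dplyr::mutate(deaths = Inf, curve_age = "all")
  scen <- tibble::tibble(name = unique(draws$scenario),
                         cap = ifelse(unique(draws$scenario) == "current", NA_real_, 10))
  structure(list(draws = draws, strata = strata, scenarios = scen,
                 cf = counterfactual_spec(), z_cf = numeric(),
                 n_draws = max(draws$draw), seed = 0L, point = point,
                 risk_model = "ier"),
            class = "burden_run")
}

random_grid <- function(n = 20, code = "AAA") {
  tiny_grid(stats::runif(n, 0, 80), population = stats::runif(n, 0, 1000), code = code)
}
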