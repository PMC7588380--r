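test_that("single-draw attributable deaths apportion deaths by population and PAF", {
  # RR exactly 2 everywhere: alpha 1 with a saturating gamma, so PAF = 0.5
  sat <- ier_draw(alpha = 1, gamma = 1e9, delta = 1, z_cf = 5)
  g_uniform <- tiny_grid(rep(15, 3), population = c(10, 50, 40))
  expect_equal(attributable_deaths_one_draw(g_uniform, sat, 1000), 500)
  # all cells at or below the counterfactual attribute nothing
  g_clean <- tiny_grid(c(2, 5), population = c(1, 1))
  expect_equal(attributable_deaths_one_draw(g_clean, ier_draw(z_cf = 5), 1000), 0)
  # two equal-population cells with RR 1 and RR 2: 1000 * (0.5*0 + 0.5*0.5)
  g_half <- tiny_grid(c(5, 15), population = c(1, 1))
  expect_equal(attributable_deaths_one_draw(g_half, sat, 1000), 250)
  # result lives in [0, deaths)
  expect_lt(attributable_deaths_one_draw(g_uniform, sat, 1000), 1000)
})

test_that("single-draw evaluation rejects stratum mismatches and bad inputs", {
  g <- tiny_grid(c(10, 20))
  d <- ier_draw(cause = "IHD", age_group = "50-69")
  expect_error(attributable_deaths_one_draw(g, d, 100, cause = "stroke"), "stroke")
  expect_error(attributable_deaths_one_draw(g, d, 100, age_group = "25-49"), "25-49")
  expect_silent(attributable_deaths_one_draw(g, d, 100, cause = "IHD", age_group = "50-69"))
  expect_error(attributable_deaths_one_draw(g, d, -5), "deaths")
  g2 <- dplyr::bind_rows(g, tiny_grid(5, code = "BBB"))
  expect_error(attributable_deaths_one_draw(g2, d, 100), "single country")
})

test_that("a degenerate Monte Carlo (one curve draw, fixed counterfactual) collapses its UI", {
  fw <- flat_world()
  run <- run_monte_carlo(fw$grid, fw$mortality, fw$curves,
                         cf = counterfactual_spec(3, 3), n_draws = 25, seed = 1)
  est <- burden_estimates(run, "world")
  expect_equal(est$ui_low, est$point)
  expect_equal(est$ui_high, est$point)
})

test_that("identical seeds give identical runs; different seeds differ", {
  fw <- flat_world()
  r1 <- run_monte_carlo(fw$grid, fw$mortality, fw$curves, n_draws = 40, seed = 99)
  r2 <- run_monte_carlo(fw$grid, fw$mortality, fw$curves, n_draws = 40, seed = 99)
  r3 <- run_monte_carlo(fw$grid, fw$mortality, fw$curves, n_draws = 40, seed = 100)
  expect_identical(r1$draws, r2$draws)
  expect_false(identical(r1$draws, r3$draws))
})

test_that("Monte-Carlo point estimate agrees with the quadrature expectation over the TMREL", {
  fw <- flat_world(E = 30, deaths = c(600, 400))
  run <- run_monte_carlo(fw$grid, fw$mortality, fw$curves, n_draws = 2000, seed = 5,
                         scenarios = who_scenarios("current"))
  d <- burden_draws(run, "world")
  # analytic expectation: E_{z_cf ~ U(2.4, 5.9)}[PAF(RR(30; z_cf))] * deaths,
  # with the closed form written out independently of the implementation
  with_curve <- function(z_cf) {
    rr <- 1 + 0.8 * (1 - exp(-0.05 * pmax(30 - z_cf, 0)^0.9))
    (rr - 1) / rr
  }
  expected <- 1000 * stats::integrate(with_curve, 2.4, 5.9)$value / (5.9 - 2.4)
  se <- stats::sd(d$deaths) / sqrt(nrow(d))
  expect_lt(abs(mean(d$deaths) - expected), 3 * se)
})

test_that("the engine validates its inputs and the curve/stratum matching", {
  fw <- flat_world()
  expect_error(run_monte_carlo(fw$grid, fw$mortality, fw$curves, n_draws = 0, seed = 1),
               "n_draws")
  expect_error(run_monte_carlo(fw$grid, fw$mortality, fw$curves, n_draws = 10),
               "seed")
  expect_error(run_monte_carlo(fw$grid, fw$mortality[0, ], fw$curves,
                               n_draws = 10, seed = 1), "empty")
  # mortality country with no exposure cells
  m2 <- dplyr::mutate(fw$mortality, country_code = "ZZZ")
  expect_error(run_monte_carlo(fw$grid, m2, fw$curves, n_draws = 10, seed = 1), "ZZZ")
  # cause without any curve draws
  m3 <- dplyr::mutate(fw$mortality, cause = "COPD", age_group = "50-69")
  expect_error(run_monte_carlo(fw$grid, m3, fw$curves, n_draws = 10, seed = 1), "COPD")
  # age-specific curves demand an exact band match
  curves_aged <- dplyr::bind_rows(
    dplyr::mutate(fw$curves, cause = "IHD", age_group = "25-49"),
    dplyr::mutate(fw$curves, cause = "IHD", age_group = "50-69"))
  m4 <- tibble::tibble(country_code = "AAA", cause = "IHD", sex = "male",
                       age_group = "80+", deaths = 10)
  expect_error(run_monte_carlo(fw$grid, m4, curves_aged, n_draws = 5, seed = 1),
               "no match")
})

test_that("aggregation sums per-draw vectors across countries, regions and world", {
  per_draw <- tidyr::expand_grid(scenario = "current",
                                 country_code = c("AAA", "BBB"), draw = 1:4) |>
    dplyr::mutate(attributable = ifelse(country_code == "AAA", 100, 200))
  run <- fake_run(per_draw)
  rm1 <- tibble::tibble(country_code = c("AAA", "BBB"), who_region = "EUR")
  reg <- burden_estimates(run, "region", rm1)
  expect_equal(reg$point, 300)  # constant draws 100 + 200
  # a single region containing every country equals the world
  expect_equal(reg$point, burden_estimates(run, "world")$point)
  # per-draw conservation across levels
  expect_equal(sum(burden_draws(run, "country")$deaths),
               sum(burden_draws(run, "world")$deaths))
  # unmapped country is rejected by code
  rm2 <- tibble::tibble(country_code = "AAA", who_region = "EUR")
  expect_error(burden_draws(run, "region", rm2), "BBB")
})

test_that("percent reduction is the mean of per-draw reductions, not the ratio of means", {
  per_draw <- dplyr::bind_rows(
    tibble::tibble(scenario = "current", country_code = "AAA", draw = 1:2,
                   attributable = c(100, 200)),
    tibble::tibble(scenario = "AQG", country_code = "AAA", draw = 1:2,
                   attributable = c(80, 120)))
  run <- fake_run(per_draw)
  red <- percent_reduction(run, "world")
  # mean of (20%, 40%) = 30%, distinct from 100*(1 - 200/300) = 33.3%
  expect_equal(red$point[red$scenario == "AQG"], 30)
  expect_equal(red$point[red$scenario == "current"], 0)
  expect_equal(red$ui_low[red$scenario == "current"], 0)
})

test_that("a zero current-level draw makes the reduction undefined, not zero", {
  per_draw <- dplyr::bind_rows(
    tibble::tibble(scenario = "current", country_code = "AAA", draw = 1:2,
                   attributable = c(0, 100)),
    tibble::tibble(scenario = "AQG", country_code = "AAA", draw = 1:2,
                   attributable = c(0, 50)))
  run <- fake_run(per_draw)
  red <- percent_reduction(run, "world")
  expect_true(is.na(red$point[red$scenario == "AQG"]))
  expect_true(is.na(red$ui_low[red$scenario == "AQG"]))
})

test_that("death totals convert to rates per 100,000", {
  est <- tibble::tibble(scenario = "current", unit = "AAA",
                        point = 500, ui_low = 400, ui_high = 600)
  out <- deaths_per_100k(est, 1e6)
  expect_equal(out$point, 50)
  expect_equal(out$ui_low, 40)
  expect_equal(deaths_per_100k(dplyr::mutate(est, point = 0), 1e6)$point, 0)
  expect_error(deaths_per_100k(est, 0), "> 0")
  expect_error(deaths_per_100k(est, tibble::tibble(unit = "BBB", population = 1)),
               "AAA")
  pops <- tibble::tibble(country_code = c("AAA", "BBB"), population = c(1e6, 3e6))
  rm <- tibble::tibble(country_code = c("AAA", "BBB"), who_region = "EUR")
  expect_equal(population_by_unit(pops, "world")$population, 4e6)
  expect_equal(population_by_unit(pops, "region", rm)$population, 4e6)
})

test_that("the GEMM engine path agrees with direct hazard-ratio evaluation", {
  g <- tiny_grid(c(8, 30, 60), population = c(100, 300, 600))
  m <- tibble::tibble(country_code = "AAA", cause = "LRI", sex = "male",
                      age_group = "all", deaths = 1000)
  gemm <- tibble::tibble(cause = "LRI", age_group = "all", draw_id = 1L,
                         theta = 0.143, knot_alpha = 1.6, mu = 15.5,
                         nu = 36.8, z_cf = 2.4)
  run <- run_monte_carlo(g, m, gemm, scenarios = who_scenarios("current"),
                         n_draws = 4, seed = 1, risk_model = "gemm")
  d <- burden_draws(run, "world")
  expected <- attributable_deaths_one_draw(g, as.list(gemm[1, ]), 1000)
  # counterfactual is fixed per curve draw, so every draw is identical
  expect_equal(d$deaths, rep(expected, 4), tolerance = 1e-12)
  # single-draw GEMM apportionment matches cell-wise PAF of the hazard ratio
  hr <- evaluate_gemm(g$pm25, as.list(gemm[1, ]))
  expect_equal(expected, 1000 * sum(g$population / 1000 * (hr - 1) / hr),
               tolerance = 1e-12)
})
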