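#' Integrated exposure-response (IER) relative risk
#'
#' Evaluates the IER family of relative-risk curves used in comparative risk
#' assessment of ambient PM2.5:
#' \deqn{RR(z) = 1 + \alpha (1 - e^{-\gamma (z - z_{cf})^{\delta}})}
#' for exposures above the counterfactual concentration \eqn{z_{cf}}, and
#' exactly 1 at or below it (no benefit is extrapolated below the
#' counterfactual). The curve is continuous, non-decreasing in `z` and
#' bounded above by `1 + alpha`.
#'
#' @param z Annual-mean PM2.5 concentration(s), ug/m3. Vectorised.
#' @param draw A single IER parameter draw: a list or one-row data frame
#'   with numeric fields `alpha` (>= 0), `gamma` (>= 0), `delta` (> 0) and
#'   `z_cf` (>= 0, ug/m3). Extra fields (`cause`, `age_group`, `draw_id`)
#'   are ignored here and used by the burden engine for matching.
#'
#' @return Numeric vector of relative risks (>= 1), same length as `z`.
#' @seealso [evaluate_gemm()], [paf()]
#' @examples
#' d <- list(alpha = 1, gamma = 0.1, delta = 1, z_cf = 5)
#' evaluate_ier(c(3, 5, 15), d)
#' @export
evaluate_ier <- function(z, draw) {
  draw <- as.list(draw)
  check_conc(z)
  for (f in c("alpha", "gamma", "delta", "z_cf")) {
    v <- draw[[f]]
    if (is.null(v) || length(v) != 1L || !is.numeric(v) || !is.finite(v)) {
      rlang::abort(sprintf("IER draw field `%s` must be a single finite number", f))
    }
  }
  if (draw$alpha < 0) rlang::abort("IER draw field `alpha` must be >= 0")
  if (draw$gamma < 0) rlang::abort("IER draw field `gamma` must be >= 0")
  if (draw$delta <= 0) rlang::abort("IER draw field `delta` must be > 0")
  if (draw$z_cf < 0) rlang::abort("IER draw field `z_cf` must be >= 0")
  ier_rr(z, draw$alpha, draw$gamma, draw$delta, draw$z_cf)
}

# vectorised core, no validation; z and parameters recycle as usual
ier_rr <- function(z, alpha, gamma, delta, z_cf) {
  excess <- pmax(z - z_cf, 0)
  1 + alpha * (1 - exp(-gamma * excess^delta))
}

#' Global Exposure Mortality Model (GEMM) hazard ratio
#'
#' Evaluates the GEMM hazard-ratio curve, an alternative to the IER fit only
#' to outdoor-PM2.5 cohorts:
#' \deqn{HR(z) = \exp\{\theta \, \log(1 + \Delta z/\alpha) \, \omega(\Delta z)\}}
#' with \eqn{\Delta z = \max(z - z_{cf}, 0)} and logistic weight
#' \eqn{\omega(\Delta z) = 1/(1 + e^{-(\Delta z - \mu)/\nu})}. The hazard
#' ratio equals 1 at the counterfactual and is non-decreasing in `z` for
#' `theta > 0`.
#'
#' @param z Annual-mean PM2.5 concentration(s), ug/m3. Vectorised.
#' @param draw A single GEMM parameter draw: list or one-row data frame with
#'   `theta` (log-hazard coefficient), `knot_alpha` (> 0, ug/m3 scale inside
#'   the log), `mu` (ug/m3, logistic centre), `nu` (!= 0, ug/m3, logistic
#'   width) and `z_cf` (>= 0; the model's fixed counterfactual, 2.4 ug/m3 in
#'   the published fit). `se_theta` may be present and is ignored here.
#'
#' @return Numeric vector of hazard ratios, same length as `z`.
#' @examples
#' d <- list(theta = 0.143, knot_alpha = 1.6, mu = 15.5, nu = 36.8, z_cf = 2.4)
#' evaluate_gemm(c(2.4, 12.4, 50), d)
#' @export
evaluate_gemm <- function(z, draw) {
  draw <- as.list(draw)
  check_conc(z)
  for (f in c("theta", "knot_alpha", "mu", "nu", "z_cf")) {
    v <- draw[[f]]
    if (is.null(v) || length(v) != 1L || !is.numeric(v) || !is.finite(v)) {
      rlang::abort(sprintf("GEMM draw field `%s` must be a single finite number", f))
    }
  }
  if (draw$nu == 0) rlang::abort("GEMM draw field `nu` must be non-zero (degenerate logistic weight)")
  if (draw$knot_alpha <= 0) rlang::abort("GEMM draw field `knot_alpha` must be > 0")
  if (draw$z_cf < 0) rlang::abort("GEMM draw field `z_cf` must be >= 0")
  gemm_hr(z, draw$theta, draw$knot_alpha, draw$mu, draw$nu, draw$z_cf)
}

gemm_hr <- function(z, theta, knot_alpha, mu, nu, z_cf) {
  dz <- pmax(z - z_cf, 0)
  w <- 1 / (1 + exp(-(dz - mu) / nu))
  exp(theta * log1p(dz / knot_alpha) * w)
}

#' Population attributable fraction from a relative risk
#'
#' The share of deaths in an exposed population attributable to the
#' exposure, `PAF = (RR - 1) / RR`. Zero at `RR = 1`, strictly increasing,
#' bounded above by 1. Relative risks below 1 are rejected: the supported
#' curves never return sub-unity risk, so such an input signals an upstream
#' bug rather than a protective exposure.
#'
#' @param rr Relative risk(s), each >= 1. Vectorised.
#' @return Attributable fraction(s) in `[0, 1)`.
#' @examples
#' paf(c(1, 1.25, 2))
#' @export
paf <- function(rr) {
  if (!is.numeric(rr) || any(!is.finite(rr))) {
    rlang::abort("`rr` must be finite numeric")
  }
  if (any(rr < 1)) {
    rlang::abort(sprintf("`rr` must be >= 1 (got %g); sub-unity risk signals an upstream bug",
                         min(rr)))
  }
  (rr - 1) / rr
}

check_conc <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z))) {
    rlang::abort("`z` must be finite numeric (ug/m3)")
  }
  if (any(z < 0)) {
    rlang::abort(sprintf("`z` must be >= 0 ug/m3 (got %g)", min(z)))
  }
  invisible(z)
}

# Column requirements for risk-parameter draw tables, per model.
curve_cols <- list(
  ier  = c("cause", "age_group", "draw_id", "alpha", "gamma", "delta", "z_cf"),
  gemm = c("cause", "age_group", "draw_id", "theta", "knot_alpha", "mu", "nu", "z_cf")
)

#' Validate a table of risk-curve parameter draws
#'
#' Checks the draw table consumed by [run_monte_carlo()]: required columns
#' for the chosen model, parameter-range invariants, recognised cause
#' labels, and that draws are uniquely identified within each cause/age
#' stratum.
#'
#' @param curves Data frame of parameter draws, one row per draw per
#'   cause/age stratum. IER columns: `cause`, `age_group`, `draw_id`,
#'   `alpha`, `gamma`, `delta`, `z_cf`. GEMM columns: `cause`, `age_group`,
#'   `draw_id`, `theta`, `knot_alpha`, `mu`, `nu`, `z_cf`.
#' @param model `"ier"` or `"gemm"`.
#' @return `curves`, invisibly, if valid; otherwise an error naming the
#'   offending column or row.
#' @export
validate_curves <- function(curves, model = c("ier", "gemm")) {
  model <- match.arg(model)
  need <- curve_cols[[model]]
  miss <- setdiff(need, names(curves))
  if (length(miss)) {
    rlang::abort(sprintf("curve table is missing column(s): %s", toString(miss)))
  }
  bad_cause <- setdiff(unique(curves$cause), modelled_causes)
  if (length(bad_cause)) {
    rlang::abort(sprintf("unknown cause label(s) in curve table: %s", toString(bad_cause)))
  }
  num <- setdiff(need, c("cause", "age_group"))
  for (f in num) {
    if (!is.numeric(curves[[f]]) || any(!is.finite(curves[[f]]))) {
      rlang::abort(sprintf("curve column `%s` must be finite numeric", f))
    }
  }
  if (model == "ier") {
    if (any(curves$alpha < 0)) rlang::abort("curve column `alpha` must be >= 0")
    if (any(curves$gamma < 0)) rlang::abort("curve column `gamma` must be >= 0")
    if (any(curves$delta <= 0)) rlang::abort("curve column `delta` must be > 0")
  } else {
    if (any(curves$knot_alpha <= 0)) rlang::abort("curve column `knot_alpha` must be > 0")
    if (any(curves$nu == 0)) rlang::abort("curve column `nu` must be non-zero")
  }
  if (any(curves$z_cf < 0)) rlang::abort("curve column `z_cf` must be >= 0")
  dup <- curves |>
    dplyr::count(.data$cause, .data$age_group, .data$draw_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    rlang::abort(sprintf("duplicated draw_id within cause/age stratum: %s / %s",
                         dup$cause[1], dup$age_group[1]))
  }
  invisible(curves)
}

#' The five causes of death modelled for ambient PM2.5
#'
#' Ischaemic heart disease and stroke (adults over 25, optionally with
#' age-specific curves), COPD and lung cancer (adults over 25), and acute
#' lower respiratory infection (all ages).
#' @format Character vector of cause labels.
#' @export
modelled_causes <- c("IHD", "stroke", "COPD", "lung_cancer", "LRI")

# causes restricted to ages > 25 years; LRI applies to all ages
adult_causes <- c("IHD", "stroke", "COPD", "lung_cancer")
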