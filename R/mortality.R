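#' Validate a baseline mortality table
#'
#' Baseline deaths by country, cause, sex and age group (Global Health
#' Estimates style). Causes are restricted to the five modelled causes;
#' ischaemic heart disease, stroke, COPD and lung cancer are only accepted
#' in age groups entirely above 25 years, while lower respiratory infection
#' is accepted at all ages. Age-group labels are free-form bands such as
#' `"25-49"` or `"70+"`; the lower bound is parsed from the leading integer.
#'
#' @param mortality Data frame with columns `country_code`, `cause`, `sex`
#'   (`"male"`/`"female"`), `age_group`, `deaths` (finite, >= 0).
#' @return `mortality` invisibly if valid, else an error with row context.
#' @export
validate_mortality <- function(mortality) {
  need <- c("country_code", "cause", "sex", "age_group", "deaths")
  miss <- setdiff(need, names(mortality))
  if (length(miss)) {
    rlang::abort(sprintf("mortality table is missing column(s): %s", toString(miss)))
  }
  if (nrow(mortality) == 0L) rlang::abort("mortality table is empty")
  bad_cause <- setdiff(unique(mortality$cause), modelled_causes)
  if (length(bad_cause)) {
    rlang::abort(sprintf("unknown cause label(s) in mortality table: %s (modelled causes: %s)",
                         toString(bad_cause), toString(modelled_causes)))
  }
  bad_sex <- setdiff(unique(mortality$sex), c("male", "female"))
  if (length(bad_sex)) {
    rlang::abort(sprintf("unknown sex label(s): %s", toString(bad_sex)))
  }
  if (!is.numeric(mortality$deaths) || any(!is.finite(mortality$deaths)) ||
      any(mortality$deaths < 0)) {
    rlang::abort("mortality column `deaths` must be finite and >= 0")
  }
  lower <- age_lower_bound(mortality$age_group)
  offending <- mortality$cause %in% adult_causes & !is.na(lower) & lower < 25
  if (any(offending)) {
    i <- which(offending)[1]
    rlang::abort(sprintf(
      "cause `%s` is modelled only above 25 years but appears in age band `%s` (row %d)",
      mortality$cause[i], mortality$age_group[i], i))
  }
  dup <- mortality |>
    dplyr::count(.data$country_code, .data$cause, .data$sex, .data$age_group) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    rlang::abort(sprintf("duplicated mortality stratum: %s/%s/%s/%s",
                         dup$country_code[1], dup$cause[1], dup$sex[1], dup$age_group[1]))
  }
  invisible(mortality)
}

# leading integer of an age-band label ("25-49" -> 25, "70+" -> 70); NA if unparseable
age_lower_bound <- function(age_group) {
  suppressWarnings(as.numeric(sub("^\\s*(\\d+).*$", "\\1", as.character(age_group))))
}

#' Counterfactual (TMREL) exposure distribution
#'
#' The theoretical minimum-risk exposure level below which no excess risk
#' is attributed, treated as uniformly distributed to reflect uncertainty
#' about effects of low-level exposure. The default `U(2.4, 5.9)` ug/m3 is
#' the range used with the GBD 2015 IER curves. Setting `low == high` gives
#' a fixed counterfactual (used e.g. with GEMM, anchored at 2.4 ug/m3).
#'
#' @param low,high Bounds in ug/m3, `0 <= low <= high`.
#' @return A list of class `counterfactual_spec`.
#' @examples
#' counterfactual_spec()          # U(2.4, 5.9)
#' counterfactual_spec(2.4, 2.4)  # fixed
#' @export
counterfactual_spec <- function(low = 2.4, high = 5.9) {
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L || length(high) != 1L ||
      !is.finite(low) || !is.finite(high)) {
    rlang::abort("`low` and `high` must be single finite numbers (ug/m3)")
  }
  if (low < 0 || low > high) {
    rlang::abort("counterfactual bounds must satisfy 0 <= low <= high")
  }
  structure(list(low = low, high = high, distribution = "uniform"),
            class = "counterfactual_spec")
}

#' @export
print.counterfactual_spec <- function(x, ...) {
  cat(sprintf("Counterfactual PM2.5 ~ U(%g, %g) ug/m3\n", x$low, x$high))
  invisible(x)
}

#' Validate a WHO region membership table
#'
#' @param region_map Data frame with columns `country_code` and
#'   `who_region`; regions must be among AFR, AMR, EMR, EUR, SEAR, WPR.
#' @return `region_map` invisibly if valid.
#' @export
validate_region_map <- function(region_map) {
  need <- c("country_code", "who_region")
  miss <- setdiff(need, names(region_map))
  if (length(miss)) {
    rlang::abort(sprintf("region map is missing column(s): %s", toString(miss)))
  }
  bad <- setdiff(unique(region_map$who_region), who_regions)
  if (length(bad)) {
    rlang::abort(sprintf("unknown WHO region label(s): %s (expected %s)",
                         toString(bad), toString(who_regions)))
  }
  if (anyDuplicated(region_map$country_code)) {
    rlang::abort("duplicated country_code in region map")
  }
  invisible(region_map)
}

#' The six WHO regions
#' @format Character vector: AFR, AMR, EMR, EUR, SEAR, WPR.
#' @export
who_regions <- c("AFR", "AMR", "EMR", "EUR", "SEAR", "WPR")
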