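#' Lifetime risk of diagnosed cervical cancer
#'
#' The cohort proportion ever diagnosed (by either detection mode) by age 84,
#' as a percent of all simulated women — including women who die of other
#' causes or undergo hysterectomy, so that absolute risks are additive on the
#' cases-per-100,000-women scale.
#'
#' @param x A `microsim_result` or `cohort_solution`.
#' @param ... Unused.
#' @return Percent (0–100).
#' @export
lifetime_risk <- function(x, ...) UseMethod("lifetime_risk")

#' @export
lifetime_risk.microsim_result <- function(x, ...) {
  100 * mean(x$women$diag_mode != "NONE")
}

#' @export
lifetime_risk.cohort_solution <- function(x, ...) x$lifetime_risk

#' Monte Carlo standard error of a microsimulation lifetime risk
#'
#' @param x A `microsim_result`.
#' @return Binomial standard error, in percent.
#' @export
lifetime_risk_se <- function(x) {
  p <- mean(x$women$diag_mode != "NONE")
  100 * sqrt(p * (1 - p) / x$n)
}

#' Symptomatically detected cancer rate during the delay window
#'
#' Numerator: diagnoses with mode `SYMPTOMATIC` in the half-open window
#' `[start, end)` (months since birth). Denominator: women alive, cancer-free,
#' and hysterectomy-free at the window start. A zero-length window (no delay)
#' is not applicable and returns `NA`.
#'
#' @param x A `microsim_result` or `cohort_solution`.
#' @param window Integer window `c(start, end)` in months; defaults to the
#'   delay window of the scenario the object was run under.
#' @param ... Unused.
#' @return Cases per 100,000 women at risk.
#' @export
symptomatic_rate_in_window <- function(x, window = NULL, ...) {
  UseMethod("symptomatic_rate_in_window")
}

#' @export
symptomatic_rate_in_window.microsim_result <- function(x, window = NULL, ...) {
  window <- window %||% x$window
  if (is.null(window) || window[2] <= window[1]) return(NA_real_)
  w <- x$women
  eligible <- (is.na(w$death_month) | w$death_month >= window[1]) &
    (is.na(w$hyst_month) | w$hyst_month >= window[1]) &
    (is.na(w$diag_month) | w$diag_month >= window[1])
  cases <- w$diag_mode == "SYMPTOMATIC" &
    !is.na(w$diag_month) & w$diag_month >= window[1] & w$diag_month < window[2]
  if (sum(eligible) == 0) return(NA_real_)
  1e5 * sum(cases) / sum(eligible)
}

#' @export
symptomatic_rate_in_window.cohort_solution <- function(x, window = NULL, ...) {
  window <- window %||% x$window
  if (is.null(window) || window[2] <= window[1]) return(NA_real_)
  bm <- x$by_month
  months <- bm$month >= window[1] & bm$month < window[2]
  denom <- bm$eligible_start[bm$month == window[1]]
  if (length(denom) != 1 || denom <= 0) return(NA_real_)
  1e5 * sum(bm$inc_sympt[months]) / denom
}

#' Short-term rate ratio against the guidelines-compliant comparator
#'
#' `RR = rate / comparator`; the comparator is the accumulated symptomatic
#' cancer rate for a guidelines-compliant screener under the same delay
#' (3-yearly for cytology-based analyses, 5-yearly for HPV-based analyses),
#' averaged over birth cohorts. An "X% higher" statement corresponds to
#' `(RR - 1) * 100`.
#'
#' @param rate_cell,rate_comparator Rates per 100,000 (vectorized).
#' @return The rate ratio; `NA` (with a warning) where the comparator rate is
#'   zero or missing.
#' @export
short_term_rate_ratio <- function(rate_cell, rate_comparator) {
  undefined <- is.na(rate_comparator) | rate_comparator == 0
  if (any(undefined & !is.na(rate_cell))) {
    warning("rate ratio undefined where the comparator rate is zero", call. = FALSE)
  }
  ifelse(undefined, NA_real_, rate_cell / rate_comparator)
}

#' Incremental lifetime risk and excess cases per 100,000 women
#'
#' @param lr_delay,lr_nodelay Lifetime risks in percent from the same
#'   cohort-averaged cell differing only in delay.
#' @return A tibble with `incremental_pp` (percentage points) and
#'   `excess_per_100k` (= incremental risk in proportion times 100,000).
#' @export
#' @examples
#' excess_cases_per_100k(0.342, 0.320) # 0.022 pp -> 22 per 100,000
excess_cases_per_100k <- function(lr_delay, lr_nodelay) {
  delta <- lr_delay - lr_nodelay
  tibble::tibble(incremental_pp = delta, excess_per_100k = delta * 1000)
}

#' Percent of cancers prevented relative to no screening
#'
#' @param lr_scenario,lr_noscreen Lifetime risks in percent; the no-screening
#'   reference must come from the same cohort(s) and variant.
#' @return Percent prevented; `NA` (with a warning) where the no-screening
#'   risk is zero.
#' @export
percent_prevented <- function(lr_scenario, lr_noscreen) {
  undefined <- is.na(lr_noscreen) | lr_noscreen == 0
  if (any(undefined & !is.na(lr_scenario))) {
    warning("percent prevented undefined for a zero no-screening risk", call. = FALSE)
  }
  ifelse(undefined, NA_real_, (lr_noscreen - lr_scenario) / lr_noscreen * 100)
}

#' Average a projection over the three birth cohorts
#'
#' Unweighted arithmetic mean over the 1965 / 1975 / 1985 cohorts within every
#' other grouping of the table; errors if any group is missing a cohort.
#'
#' @param data A tibble containing `birth_year`, the value column, and any
#'   number of grouping columns.
#' @param value Name of the value column (tidy-eval).
#' @param cohorts The required cohort set.
#' @return `data` collapsed over `birth_year`, with `value` replaced by its
#'   cohort mean.
#' @export
#' @examples
#' average_over_cohorts(
#'   tibble::tibble(birth_year = c(1965, 1975, 1985), risk = 1:3), risk
#' )
average_over_cohorts <- function(data, value, cohorts = c(1965L, 1975L, 1985L)) {
  value <- rlang::enquo(value)
  value_name <- rlang::as_name(value)
  keys <- setdiff(names(data), c("birth_year", value_name))
  grouped <- dplyr::group_by(data, dplyr::across(dplyr::all_of(keys)))
  bad <- dplyr::summarise(grouped,
                          ok = setequal(.data$birth_year, cohorts) &&
                            dplyr::n() == length(cohorts),
                          .groups = "drop")
  if (!all(bad$ok)) {
    stop("average_over_cohorts requires exactly one value per cohort ",
         paste(cohorts, collapse = "/"), call. = FALSE)
  }
  dplyr::summarise(grouped, !!value_name := mean(!!value), .groups = "drop")
}
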