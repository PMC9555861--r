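#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a screening schedule as a timeline
#'
#' @param object A [build_schedule()] result.
#' @param ... Unused.
#' @return A ggplot: screens by calendar year and age, with the delay window
#'   shaded.
#' @export
autoplot.screen_schedule <- function(object, ...) {
  w <- attr(object, "delay_window")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$calendar_year, y = .data$age_years,
                                    shape = .data$modality)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "Calendar year", y = "Age (years)", shape = "Modality",
                  title = "Routine screening schedule") +
    ggplot2::theme_minimal()
  if (!is.null(w) && w[["end_year"]] > w[["start_year"]]) {
    p <- p + ggplot2::annotate("rect",
                               xmin = w[["start_year"]], xmax = w[["end_year"]],
                               ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red")
  }
  p
}

#' Plot expected cancer incidence by age from a cohort solution
#'
#' @param object A [cohort_solve()] result.
#' @param ... Unused.
#' @return A ggplot of annual incident cancer mass per 100,000 by age and
#'   detection mode.
#' @export
autoplot.cohort_solution <- function(object, ...) {
  by_age <- object$by_month |>
    dplyr::mutate(age = .data$month %/% 12) |>
    dplyr::group_by(.data$age) |>
    dplyr::summarise(
      `Screen-detected` = 1e5 * sum(.data$inc_screen),
      Symptomatic = 1e5 * sum(.data$inc_sympt),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(-"age", names_to = "mode", values_to = "cases")
  ggplot2::ggplot(by_age, ggplot2::aes(.data$age, .data$cases, colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Age (years)", y = "Expected incident cancers per 100,000",
                  colour = "Detection mode") +
    ggplot2::theme_minimal()
}

#' Lifetime risk by screening frequency, modality, and delay
#'
#' @param summary A [summarize_outcomes()] tibble.
#' @return A ggplot mirroring the long-term impact panels: cohort-averaged
#'   lifetime risk against time since last screen, one line per delay arm,
#'   faceted by variant and modality.
#' @export
plot_lifetime_risk <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = factor(.data$frequency_years),
                               y = .data$lifetime_risk,
                               colour = factor(.data$delay_years),
                               group = factor(.data$delay_years))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(ggplot2::vars(.data$modality), ggplot2::vars(.data$variant)) +
    ggplot2::labs(x = "Screening frequency (years since last screen in 2020)",
                  y = "Lifetime risk of cervical cancer (%)",
                  colour = "Delay (years)") +
    ggplot2::theme_minimal()
}

#' Excess lifetime cases per 100,000 by delay arm
#'
#' @param summary A [summarize_outcomes()] tibble.
#' @return A ggplot of excess cases (versus no delay) by screening frequency
#'   and delay, faceted by variant and modality.
#' @export
plot_excess_cases <- function(summary) {
  dat <- dplyr::filter(summary, .data$delay_years > 0)
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = factor(.data$frequency_years),
                               y = .data$excess_cases_per_100k,
                               fill = factor(.data$delay_years))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(ggplot2::vars(.data$modality), ggplot2::vars(.data$variant)) +
    ggplot2::labs(x = "Screening frequency (years)",
                  y = "Excess lifetime cases per 100,000 women",
                  fill = "Delay (years)") +
    ggplot2::theme_minimal()
}

#' Short-term rate ratios versus the guidelines-compliant screener
#'
#' @param summary A [summarize_outcomes()] tibble.
#' @return A ggplot of the within-window symptomatic-cancer rate ratio by
#'   years since last screen and delay arm.
#' @export
plot_rate_ratios <- function(summary) {
  dat <- dplyr::filter(summary, .data$delay_years > 0,
                       !is.na(.data$rate_ratio_vs_compliant))
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = factor(.data$frequency_years),
                               y = .data$rate_ratio_vs_compliant,
                               colour = factor(.data$delay_years),
                               group = factor(.data$delay_years))) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(ggplot2::vars(.data$modality), ggplot2::vars(.data$variant)) +
    ggplot2::labs(x = "Years since last screen at disruption",
                  y = "Rate ratio vs guidelines-compliant screener",
                  colour = "Delay (years)") +
    ggplot2::theme_minimal()
}
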