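#' Screening policy rules
#'
#' Encodes the age window and modality-switch rule of a US-style primary
#' cervical screening policy: routine screening between `start_age` and
#' `stop_age`, cytology below `hpv_switch_age`, and (for primary-HPV
#' scenarios) HPV testing from the first scheduled screen at or after
#' `hpv_switch_age`. `disruption_start_year` anchors the delay window.
#'
#' @param start_age Age (years) at first screening eligibility.
#' @param stop_age Age (years) after which no routine screens occur. Screens
#'   at exactly `stop_age` are kept.
#' @param hpv_switch_age Age (years) from which primary-HPV scenarios use HPV
#'   testing.
#' @param disruption_start_year Calendar year the disruption begins; the
#'   scenario grid is aligned so a routine screen falls due in this year.
#' @return A list of class `policy_rules`.
#' @export
#' @examples
#' policy_rules()
policy_rules <- function(start_age = 21, stop_age = 65, hpv_switch_age = 30,
                         disruption_start_year = 2020) {
  stopifnot(start_age < hpv_switch_age, hpv_switch_age < stop_age)
  structure(
    list(
      start_age = as.integer(start_age),
      stop_age = as.integer(stop_age),
      hpv_switch_age = as.integer(hpv_switch_age),
      disruption_start_year = as.integer(disruption_start_year)
    ),
    class = "policy_rules"
  )
}

scenario_modalities <- function() c("CYTOLOGY", "HPV_PRIMARY")

#' One cell of the disruption-scenario grid
#'
#' @param birth_year Birth year of the cohort (the default grid uses 1965,
#'   1975, and 1985).
#' @param frequency_years Underlying routine screening interval in years.
#' @param modality `"CYTOLOGY"` or `"HPV_PRIMARY"`.
#' @param delay_years Length of the temporary disruption in years (0 = none).
#' @param policy A [policy_rules()] object.
#' @return A one-row tibble of class `scenario_spec` with the policy attached
#'   as an attribute.
#' @export
#' @examples
#' scenario_spec(1975, 10, "CYTOLOGY", 1)
scenario_spec <- function(birth_year, frequency_years, modality, delay_years,
                          policy = policy_rules()) {
  modality <- match.arg(modality, scenario_modalities())
  stopifnot(
    is.numeric(birth_year), length(birth_year) == 1,
    is.numeric(frequency_years), frequency_years >= 1,
    is.numeric(delay_years), delay_years >= 0
  )
  out <- tibble::tibble(
    birth_year = as.integer(birth_year),
    frequency_years = as.integer(frequency_years),
    modality = modality,
    delay_years = as.integer(delay_years)
  )
  attr(out, "policy") <- policy
  class(out) <- c("scenario_spec", class(out))
  out
}

spec_policy <- function(spec, policy = NULL) {
  if (!is.null(policy)) return(policy)
  p <- attr(spec, "policy")
  if (is.null(p)) policy_rules() else p
}

#' Build the dated routine-screening schedule for one scenario cell
#'
#' Screens are aligned backward from the screen falling due in the disruption
#' year (so that year is exactly `frequency_years` since the last screen) down
#' to the first-eligibility age; the disrupted screen is shifted to
#' `disruption year + delay_years`, subsequent screens follow at the fixed
#' frequency from that shifted anchor, and any screen that would land past
#' `stop_age` is dropped. In primary-HPV scenarios the modality is cytology
#' before `hpv_switch_age` and HPV testing from the first screen at or after
#' that age.
#'
#' @param spec A [scenario_spec()] (or any one-row data frame / list with
#'   fields `birth_year`, `frequency_years`, `modality`, `delay_years`).
#' @param policy A [policy_rules()]; defaults to the policy attached to `spec`.
#' @return A tibble of class `screen_schedule` with one row per routine screen
#'   (`calendar_year`, `age_years`, `modality`, `month` since birth) and the
#'   scenario, policy, and delay window attached as attributes. A scenario in
#'   which the delay pushes every remaining screen past `stop_age` yields an
#'   empty post-delay tail, not an error.
#' @export
#' @examples
#' build_schedule(scenario_spec(1975, 10, "CYTOLOGY", 1))
build_schedule <- function(spec, policy = NULL) {
  spec <- as.list(spec)[c("birth_year", "frequency_years", "modality", "delay_years")]
  stopifnot(!anyNA(unlist(spec[c("birth_year", "frequency_years", "delay_years")])))
  pol <- spec_policy(spec, policy)
  by <- as.integer(spec$birth_year)
  freq <- as.integer(spec$frequency_years)
  delay <- as.integer(spec$delay_years)
  modality <- match.arg(spec$modality, scenario_modalities())

  anchor_age <- pol$disruption_start_year - by
  # history: screens strictly before the disruption year, backward at the
  # screening frequency, never before first eligibility
  pre <- anchor_age - seq_len(max(0L, (anchor_age - pol$start_age) %/% freq)) * freq
  pre <- sort(pre[pre >= pol$start_age & pre <= pol$stop_age])
  # resumption: the screen due in the disruption year occurs after the delay;
  # later screens keep the frequency from the shifted anchor, dropped past
  # stop_age
  first_post <- anchor_age + delay
  post <- first_post + seq(0L, by = freq,
                           length.out = max(0L, (pol$stop_age - first_post) %/% freq + 1L))
  post <- post[post >= pol$start_age & post <= pol$stop_age]

  ages <- c(pre, post)
  event_modality <- if (modality == "HPV_PRIMARY") {
    ifelse(ages >= pol$hpv_switch_age, "HPV_PRIMARY", "CYTOLOGY")
  } else {
    rep("CYTOLOGY", length(ages))
  }
  out <- tibble::tibble(
    calendar_year = by + ages,
    age_years = as.integer(ages),
    modality = event_modality,
    month = as.integer(ages * 12L)
  )
  attr(out, "spec") <- spec
  attr(out, "policy") <- pol
  attr(out, "delay_window") <- c(
    start_year = pol$disruption_start_year,
    end_year = pol$disruption_start_year + delay
  )
  attr(out, "birth_year") <- by
  class(out) <- c("screen_schedule", class(out))
  out
}

#' Age at the last routine screen of a schedule
#'
#' @param schedule A [build_schedule()] result.
#' @return The maximum screening age in years, or `NA` for a schedule with no
#'   screens.
#' @export
last_routine_screen_age <- function(schedule) {
  if (nrow(schedule) == 0) return(NA_integer_)
  max(schedule$age_years)
}

#' The delay window of a schedule, in months since birth
#'
#' Half-open window `[start, end)`: a diagnosis in the month screening
#' resumes belongs to post-window time.
#'
#' @param schedule A [build_schedule()] result.
#' @return Integer vector `c(start, end)` in months since birth, or `NULL`
#'   for a zero-length delay.
#' @export
delay_window_months <- function(schedule) {
  w <- attr(schedule, "delay_window")
  by <- attr(schedule, "birth_year")
  if (is.null(w) || w[["end_year"]] == w[["start_year"]]) return(NULL)
  c(
    start = (w[["start_year"]] - by) * 12L,
    end = (w[["end_year"]] - by) * 12L
  )
}

#' Default configuration of the scenario grid
#'
#' @param cohorts Birth years.
#' @param frequencies Screening intervals in years.
#' @param modalities Primary screening modalities.
#' @param delays Disruption lengths in years.
#' @param policy A [policy_rules()].
#' @return A list of class `grid_config`.
#' @export
grid_config <- function(cohorts = c(1965L, 1975L, 1985L),
                        frequencies = c(1L, 3L, 5L, 10L),
                        modalities = scenario_modalities(),
                        delays = c(0L, 1L, 2L, 5L),
                        policy = policy_rules()) {
  if (!all(modalities %in% scenario_modalities())) {
    stop("unknown modality in grid configuration", call. = FALSE)
  }
  if (any(frequencies < 1) || any(delays < 0)) {
    stop("invalid frequency or delay in grid configuration", call. = FALSE)
  }
  structure(
    list(
      cohorts = as.integer(cohorts), frequencies = as.integer(frequencies),
      modalities = modalities, delays = as.integer(delays), policy = policy
    ),
    class = "grid_config"
  )
}

#' Expand the scenario grid
#'
#' Full cross-product of cohort, frequency, modality, and delay, plus one
#' no-screening reference cell per cohort (used by the percent-prevented
#' statistic).
#'
#' @param config A [grid_config()].
#' @return A tibble with one row per scenario cell; no-screening reference
#'   rows carry `screening = FALSE` and `NA` frequency/modality/delay.
#' @export
#' @examples
#' nrow(build_grid(grid_config())) # 96 scenario cells + 3 references
build_grid <- function(config = grid_config()) {
  cells <- tidyr::expand_grid(
    birth_year = config$cohorts,
    frequency_years = config$frequencies,
    modality = config$modalities,
    delay_years = config$delays
  )
  cells$screening <- TRUE
  refs <- tibble::tibble(
    birth_year = config$cohorts,
    frequency_years = NA_integer_,
    modality = NA_character_,
    delay_years = NA_integer_,
    screening = FALSE
  )
  out <- dplyr::bind_rows(cells, refs)
  out <- dplyr::mutate(
    out,
    cell_id = dplyr::if_else(
      screening,
      sprintf("%d_%dy_%s_d%d", birth_year, frequency_years,
              tolower(modality), delay_years),
      sprintf("%d_noscreen", birth_year)
    ),
    .before = 1
  )
  attr(out, "policy") <- config$policy
  out
}

#' Empty schedule (no-screening reference)
#'
#' @param birth_year Cohort birth year.
#' @param policy A [policy_rules()].
#' @return A zero-row `screen_schedule`.
#' @export
empty_schedule <- function(birth_year, policy = policy_rules()) {
  out <- tibble::tibble(
    calendar_year = integer(), age_years = integer(),
    modality = character(), month = integer()
  )
  attr(out, "spec") <- list(birth_year = as.integer(birth_year),
                            frequency_years = NA_integer_,
                            modality = NA_character_, delay_years = 0L)
  attr(out, "policy") <- policy
  attr(out, "delay_window") <- c(start_year = policy$disruption_start_year,
                                 end_year = policy$disruption_start_year)
  attr(out, "birth_year") <- as.integer(birth_year)
  class(out) <- c("screen_schedule", class(out))
  out
}

#' Schedule for one row of the scenario grid
#'
#' @param cell One row of [build_grid()] output.
#' @param policy A [policy_rules()].
#' @return A `screen_schedule`.
#' @export
schedule_for_cell <- function(cell, policy = policy_rules()) {
  if (!isTRUE(cell$screening)) {
    empty_schedule(cell$birth_year, policy)
  } else {
    build_schedule(cell, policy = policy)
  }
}

#' Export schedules of a grid as a tidy audit table
#'
#' @param grid A [build_grid()] tibble.
#' @param policy A [policy_rules()].
#' @return A tibble with one row per scheduled screen across all cells.
#' @export
grid_schedule_table <- function(grid, policy = attr(grid, "policy") %||% policy_rules()) {
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    sch <- schedule_for_cell(cell, policy)
    if (nrow(sch) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(cell_id = cell$cell_id), tibble::as_tibble(sch))
  })
}
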