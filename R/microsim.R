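state_code_labels <- function() {
  c("HEALTHY", "HPV_INFECTED", "PRECANCER", "PRECLINICAL_CANCER",
    "DIAGNOSED_CANCER", "HYSTERECTOMY", "DEAD_OTHER") # codes 0..6
}
genotype_code_labels <- function() c("NONE", "HPV16_18", "OTHER_HR") # codes 0..2

validate_schedule_for_simulation <- function(schedule) {
  pol <- attr(schedule, "policy") %||% policy_rules()
  if (nrow(schedule) == 0) return(invisible(schedule))
  if (any(schedule$month >= 84 * 12) || any(schedule$age_years < pol$start_age)) {
    stop("schedule has events after age 84 or before first screening eligibility",
         call. = FALSE)
  }
  if (is.unsorted(schedule$month, strictly = TRUE)) {
    stop("schedule events must be strictly increasing in time", call. = FALSE)
  }
  invisible(schedule)
}

engine_inputs <- function(schedule, params, demography, vaccination, init) {
  validate_params(params)
  validate_schedule_for_simulation(schedule)
  mod <- expand_model(params, demography, vaccination)
  g <- genotype_levels()
  init_state <- 0L; init_month <- 0L; init_gt <- 0L; init_occ <- FALSE
  if (!is.null(init)) {
    init_month <- as.integer(init$month %||% 0L)
    st <- init$state %||% "HEALTHY"
    if (st == "PRECLINICAL_CANCER") {
      init_state <- 3L
      init_gt <- match(init$genotype %||% "hpv16_18", g)
      init_occ <- isTRUE(init$occult)
    } else if (st != "HEALTHY") {
      stop("unsupported initial state: ", st, call. = FALSE)
    }
  }
  list(
    n_months = mod$n_months,
    acq16 = mod$acq16, acq_oth = mod$acq_oth,
    death_cdf = 1 - cumprod(1 - mod$pd),
    hyst_cdf = 1 - cumprod(1 - mod$ph),
    coverage = mod$coverage, ve = mod$ve,
    c16 = unname(params$clearance[g[1]]), c_oth = unname(params$clearance[g[2]]),
    pi16 = unname(params$progression_to_precancer[g[1]]),
    pi_oth = unname(params$progression_to_precancer[g[2]]),
    rho16 = unname(params$regression_from_precancer[g[1]]),
    rho_oth = unname(params$regression_from_precancer[g[2]]),
    tau = params$progression_to_cancer,
    sigma = params$symptomatic_detection_rate,
    occult_frac = params$occult_fraction,
    screen_month = as.integer(schedule$month),
    screen_modality = as.integer(schedule$modality == "HPV_PRIMARY"),
    init_state = init_state, init_month = init_month,
    init_gt = init_gt, init_occ = init_occ
  )
}

#' Simulate a cohort of individual life courses
#'
#' Runs the Monte Carlo engine for `n` women from birth to age 84 under one
#' scenario's screening schedule. Each woman's random stream is keyed by
#' `(seed, birth cohort, woman index)`, so rerunning any scenario for the same
#' cohort and seed reuses identical latent randomness — the common-random-
#' numbers design that makes differences between delay arms reflect the delay
#' itself rather than sampling noise.
#'
#' @param schedule A [build_schedule()] / [empty_schedule()] result.
#' @param params An `nh_params` object.
#' @param demography A [make_demography()] tibble.
#' @param vaccination A [make_vaccination_profile()] row.
#' @param n Number of women.
#' @param seed Master seed (integer).
#' @param record_events Keep per-event logs (state changes and screens); only
#'   sensible for small `n`.
#' @param init Optional initial condition (see [cohort_solve()]).
#' @param woman_offset Index of the first woman's stream; lets callers split
#'   a cohort across calls without stream reuse.
#' @return A list of class `microsim_result`: `women` (one row per woman with
#'   diagnosis mode/month/genotype, death and hysterectomy months, vaccination
#'   status), the scenario `window`, and optional `events` / `screens` logs.
#' @export
#' @examples
#' p <- make_variant("short_dwell", calibrate = FALSE)
#' sim <- simulate_cohort(
#'   build_schedule(scenario_spec(1975, 3, "CYTOLOGY", 0)),
#'   p, make_demography(), make_vaccination_profile(1975), n = 500, seed = 7
#' )
#' lifetime_risk(sim)
simulate_cohort <- function(schedule, params, demography, vaccination,
                            n, seed, record_events = FALSE, init = NULL,
                            woman_offset = 0) {
  inp <- engine_inputs(schedule, params, demography, vaccination, init)
  birth_year <- attr(schedule, "birth_year") %||% 0L
  raw <- .sim_cohort_cpp(
    n = as.integer(n), n_months = inp$n_months,
    acq16 = inp$acq16, acq_oth = inp$acq_oth,
    death_cdf = inp$death_cdf, hyst_cdf = inp$hyst_cdf,
    coverage = inp$coverage, ve = inp$ve,
    c16 = inp$c16, c_oth = inp$c_oth, pi16 = inp$pi16, pi_oth = inp$pi_oth,
    rho16 = inp$rho16, rho_oth = inp$rho_oth, tau = inp$tau, sigma = inp$sigma,
    occult_frac = inp$occult_frac,
    cyto_sens_prec = params$cyto_sens_precancer,
    cyto_sens_cancer = params$cyto_sens_cancer,
    cyto_spec = params$cyto_spec,
    hpv_sens = params$hpv_sens, hpv_spec = params$hpv_spec,
    colpo_sens = params$colposcopy_sens,
    colpo_comp = params$colposcopy_compliance,
    treat_comp = params$treatment_compliance,
    screen_month = inp$screen_month, screen_modality = inp$screen_modality,
    init_state = inp$init_state, init_month = inp$init_month,
    init_genotype = inp$init_gt, init_occult = inp$init_occ,
    master_seed = as.double(seed), cohort_key = as.double(birth_year),
    woman_offset = as.double(woman_offset),
    record_events = record_events
  )
  women <- tibble::tibble(
    woman = seq_len(n) - 1L + as.integer(woman_offset),
    diag_mode = c("NONE", "SCREEN_DETECTED", "SYMPTOMATIC")[raw$diag_mode + 1L],
    diag_month = ifelse(raw$diag_month < 0, NA_integer_, raw$diag_month),
    diag_genotype = genotype_code_labels()[raw$diag_genotype + 1L],
    death_month = ifelse(raw$death_month < 0, NA_integer_, raw$death_month),
    hyst_month = ifelse(raw$hyst_month < 0, NA_integer_, raw$hyst_month),
    vaccinated = raw$vaccinated == 1L
  )
  out <- list(
    women = women, n = as.integer(n), seed = as.integer(seed),
    birth_year = birth_year,
    variant = params$variant_name,
    window = delay_window_months(schedule),
    schedule = schedule
  )
  if (record_events) {
    out$events <- tibble::as_tibble(raw$state_log)
    out$events$state <- state_code_labels()[out$events$state + 1L]
    out$events$genotype <- genotype_code_labels()[out$events$genotype + 1L]
    out$events$occult <- out$events$occult == 1L
    out$screens <- tibble::as_tibble(raw$screen_log)
    out$screens$kind <- c("ROUTINE", "SURVEILLANCE")[out$screens$kind + 1L]
    out$screens$modality <- dplyr::case_match(out$screens$modality,
                                              0L ~ "CYTOLOGY", 1L ~ "HPV_PRIMARY",
                                              .default = NA_character_)
    out$screens$state <- state_code_labels()[out$screens$state + 1L]
  }
  class(out) <- "microsim_result"
  out
}

#' @export
print.microsim_result <- function(x, ...) {
  cat("<microsim_result>", x$n, "women, variant", x$variant %||% "?", "\n")
  cat(sprintf("  lifetime risk: %.3f%% (MC SE %.3f)\n",
              lifetime_risk(x), lifetime_risk_se(x)))
  invisible(x)
}

#' Tidy per-woman outcomes of a microsimulation
#'
#' @param x A `microsim_result`.
#' @param ... Unused.
#' @return The per-woman outcome tibble.
#' @export
tidy.microsim_result <- function(x, ...) x$women

#' @export
glance.microsim_result <- function(x, ...) {
  tibble::tibble(
    variant = x$variant %||% NA_character_,
    n = x$n,
    lifetime_risk_pct = lifetime_risk(x),
    lifetime_risk_se_pct = lifetime_risk_se(x),
    symptomatic_rate_window = symptomatic_rate_in_window(x)
  )
}

#' Simulate full life courses with event logging
#'
#' A thin wrapper over [simulate_cohort()] with event recording on, returning
#' the dated state path and screening history of each woman — the trajectory
#' event log. Identical seeds and schedules reproduce identical trajectories.
#'
#' @inheritParams simulate_cohort
#' @return A list of class `life_course`: `events` (one row per state change:
#'   woman, month, state, genotype, occult), `screens` (one row per screening
#'   or surveillance contact), and `women` (end-of-follow-up summary with the
#'   diagnosis record and end reason).
#' @export
#' @examples
#' p <- make_variant("short_dwell", calibrate = FALSE)
#' lc <- simulate_life_course(
#'   build_schedule(scenario_spec(1975, 3, "CYTOLOGY", 0)),
#'   p, make_demography(), make_vaccination_profile(1975), n = 5, seed = 42
#' )
#' lc$events
simulate_life_course <- function(schedule, params, demography, vaccination,
                                 seed, n = 1, init = NULL) {
  sim <- simulate_cohort(schedule, params, demography, vaccination,
                         n = n, seed = seed, record_events = TRUE, init = init)
  women <- dplyr::mutate(
    sim$women,
    end_reason = dplyr::if_else(is.na(death_month), "REACHED_84", "DEAD_OTHER"),
    end_month = dplyr::coalesce(death_month, 84L * 12L)
  )
  structure(
    list(events = sim$events, screens = sim$screens, women = women,
         birth_year = sim$birth_year, seed = sim$seed),
    class = "life_course"
  )
}

#' @export
print.life_course <- function(x, ...) {
  cat("<life_course>", nrow(x$women), "women,", nrow(x$events), "state changes,",
      nrow(x$screens), "screening contacts\n")
  invisible(x)
}

#' Export a trajectory event log as a tidy table
#'
#' @param x A `life_course` object.
#' @param ... Unused.
#' @return One row per state change, with diagnosis / end-of-follow-up fields
#'   joined per woman.
#' @export
tidy.life_course <- function(x, ...) {
  dplyr::left_join(
    x$events,
    dplyr::select(x$women, woman, diag_mode, diag_month, end_reason, end_month),
    by = "woman"
  )
}
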