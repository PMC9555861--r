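# Shared screening-cascade probability algebra -------------------------------
#
# Both the deterministic solver and the vectorized R cascade draw their branch
# probabilities from these helpers, so the two stay consistent by construction;
# the C++ engine mirrors them and is checked against the solver in tests.

# probability a screen of the given modality ends in a colposcopy referral;
# stage is one of "healthy", "hpv", "prec", "precl"; vectorized
referral_prob <- function(stage, genotype, occult, modality, params) {
  cyto_pos <- function() {
    p <- rep(1 - params$cyto_spec, length(stage))
    p[stage == "prec"] <- ifelse(occult[stage == "prec"], 0, params$cyto_sens_precancer)
    p[stage == "precl"] <- ifelse(occult[stage == "precl"], 0, params$cyto_sens_cancer)
    p
  }
  hpv_pos <- ifelse(stage == "healthy", 1 - params$hpv_spec, params$hpv_sens)
  out <- numeric(length(stage))
  is_cyto <- modality == "CYTOLOGY"
  # cytology primary: ASCUS+ cytology and reflex HPV-positive
  pc <- cyto_pos()
  out[is_cyto] <- (pc * hpv_pos)[is_cyto]
  # HPV primary: 16/18 positives referred directly, other-HR positives only
  # after ASCUS+ triage cytology; analytic false positives are called other-HR
  direct <- stage != "healthy" & genotype == "hpv16_18"
  triage <- pc
  out[!is_cyto] <- (hpv_pos * ifelse(direct, 1, triage))[!is_cyto]
  out
}

# expand age-year-indexed inputs to the 1008 monthly cycles (birth to age 84)
expand_model <- function(params, demography, vaccination) {
  validate_demography(demography)
  n_months <- 84L * 12L
  rep12 <- function(x) rep(x, each = 12)[seq_len(n_months)]
  list(
    n_months = n_months,
    acq16 = rep12(params$hpv_incidence$hpv16_18),
    acq_oth = rep12(params$hpv_incidence$other_hr),
    pd = rep12(demography$p_death_month),
    ph = rep12(demography$p_hyst_month),
    coverage = vaccination$coverage,
    ve = vaccination$efficacy_16_18
  )
}

# --------------------------------------------------------------------------

#' Deterministic cohort solver (verification oracle)
#'
#' Forward-propagates the full health-state distribution of a birth cohort
#' through the identical monthly transition structure the Monte Carlo engine
#' samples from: symptomatic presentation of a preclinical cancer resolves at
#' the start of each cycle (before any scheduled contact, so it never
#' coincides with an attended screen), screens act next, detected-but-
#' untreated lesions sit in a 12-month surveillance countdown, and the
#' remaining competing events resolve in the fixed order death >
#' hysterectomy > disease transition. No
#' randomness is involved, so its expected incidence and lifetime risk serve
#' as the oracle for the microsimulation.
#'
#' @param schedule A [build_schedule()] or [empty_schedule()] result.
#' @param params An `nh_params` object.
#' @param demography A [make_demography()] tibble.
#' @param vaccination A [make_vaccination_profile()] row; cohorts with partial
#'   coverage are solved as a mixture of a vaccinated and an unvaccinated
#'   stratum.
#' @param init Optional starting condition, a list with elements `state`
#'   (`"HEALTHY"` or `"PRECLINICAL_CANCER"`), `month` (cycles since birth),
#'   `genotype`, and `occult`; the default is the whole cohort healthy at
#'   birth. Used for analytic verification settings.
#' @return A list of class `cohort_solution` with elements `by_month`
#'   (eligible mass at month start, incident screen-detected and symptomatic
#'   cancer mass per month), `occupancy` (state-occupancy fractions at each
#'   month start), `lifetime_risk` (percent ever diagnosed by age 84),
#'   `diagnosed_by_genotype`, and the inputs' metadata.
#' @export
#' @examples
#' sol <- cohort_solve(
#'   empty_schedule(1975), make_variant("short_dwell", calibrate = FALSE),
#'   make_demography(), make_vaccination_profile(1975)
#' )
#' lifetime_risk(sol)
cohort_solve <- function(schedule, params, demography, vaccination,
                         init = NULL) {
  validate_params(params)
  mod <- expand_model(params, demography, vaccination)
  cov <- mod$coverage
  if (cov > 0 && cov < 1) {
    a <- cohort_solve_stratum(schedule, params, mod, vaccinated = FALSE, init = init)
    b <- cohort_solve_stratum(schedule, params, mod, vaccinated = TRUE, init = init)
    sol <- mix_solutions(a, b, 1 - cov, cov)
  } else {
    sol <- cohort_solve_stratum(schedule, params, mod, vaccinated = cov >= 1, init = init)
  }
  sol$schedule <- schedule
  sol$window <- delay_window_months(schedule)
  sol$variant <- params$variant_name
  class(sol) <- "cohort_solution"
  sol
}

mix_solutions <- function(a, b, wa, wb) {
  list(
    by_month = tibble::tibble(
      month = a$by_month$month,
      eligible_start = wa * a$by_month$eligible_start + wb * b$by_month$eligible_start,
      inc_screen = wa * a$by_month$inc_screen + wb * b$by_month$inc_screen,
      inc_sympt = wa * a$by_month$inc_sympt + wb * b$by_month$inc_sympt
    ),
    occupancy = dplyr::bind_cols(
      tibble::tibble(month = a$occupancy$month),
      as.data.frame(wa * as.matrix(a$occupancy[-1]) + wb * as.matrix(b$occupancy[-1]))
    ),
    lifetime_risk = wa * a$lifetime_risk + wb * b$lifetime_risk,
    diagnosed_by_genotype = wa * a$diagnosed_by_genotype + wb * b$diagnosed_by_genotype
  )
}

cohort_solve_stratum <- function(schedule, params, mod, vaccinated, init = NULL) {
  n_months <- mod$n_months
  acq16 <- mod$acq16 * (if (vaccinated) 1 - mod$ve else 1)
  acq_oth <- mod$acq_oth
  if (any(acq16 + acq_oth > 1)) {
    stop("non-stochastic cycle: acquisition probabilities sum above 1", call. = FALSE)
  }

  g <- genotype_levels()
  pi_g <- params$progression_to_precancer[g]
  c_g <- params$clearance[g]
  rho_g <- params$regression_from_precancer[g]
  tau <- params$progression_to_cancer
  sigma <- params$symptomatic_detection_rate
  occ <- params$occult_fraction
  comp <- params$colposcopy_compliance
  csens <- params$colposcopy_sens
  treat <- params$treatment_compliance

  # phase index 1 = not under surveillance, p in 2..13 = visit due in p-1 months
  n_phase <- 13L
  healthy <- 1; hpv <- c(0, 0)
  prec <- array(0, dim = c(2, 2, n_phase))   # genotype x occult(no, yes) x phase
  precl <- array(0, dim = c(2, 2, n_phase))
  hyst <- 0; dead <- 0; diag_screen <- 0; diag_sympt <- 0
  diag_by_g <- c(hpv16_18 = 0, other_hr = 0)

  start_month <- 0L
  if (!is.null(init)) {
    start_month <- as.integer(init$month %||% 0L)
    state <- init$state %||% "HEALTHY"
    if (state == "PRECLINICAL_CANCER") {
      gi <- match(init$genotype %||% "hpv16_18", g)
      oi <- if (isTRUE(init$occult)) 2L else 1L
      healthy <- 0; precl[gi, oi, 1] <- 1
    } else if (state != "HEALTHY") {
      stop("unsupported initial state: ", state, call. = FALSE)
    }
  }

  screen_at <- schedule$month
  screen_mod <- schedule$modality

  eligible_start <- numeric(n_months)
  inc_screen <- numeric(n_months)
  inc_sympt <- numeric(n_months)
  occ_names <- c("healthy", "hpv_infected", "precancer", "preclinical",
                 "diagnosed", "hysterectomy", "dead_other")
  occupancy <- matrix(0, n_months, length(occ_names),
                      dimnames = list(NULL, occ_names))

  # referral probabilities only depend on stage/genotype/occult/modality;
  # precompute the detection (referred x attended x seen) probability grids
  det_grid <- function(stage, modality) {
    gr <- expand.grid(gi = 1:2, oi = 1:2)
    p <- referral_prob(rep(stage, 4), g[gr$gi], gr$oi == 2, modality, params)
    matrix(p * comp * csens, 2, 2)
  }
  det <- list(
    CYTOLOGY = list(prec = det_grid("prec", "CYTOLOGY"),
                    precl = det_grid("precl", "CYTOLOGY")),
    HPV_PRIMARY = list(prec = det_grid("prec", "HPV_PRIMARY"),
                       precl = det_grid("precl", "HPV_PRIMARY"))
  )
  det_surv <- comp * csens

  for (m in seq.int(start_month, n_months - 1L)) {
    mi <- m + 1L
    eligible_start[mi] <- healthy + sum(hpv) + sum(prec) + sum(precl)
    occupancy[mi, ] <- c(healthy, sum(hpv), sum(prec), sum(precl),
                         diag_screen + diag_sympt, hyst, dead)

    # -- symptomatic presentation resolves at the start of the cycle, before
    # any scheduled contact (so a symptomatic diagnosis never coincides with
    # an attended screen, and zero-sensitivity screening reproduces the
    # no-screening risk exactly)
    sympt <- precl * sigma
    precl <- precl * (1 - sigma)
    s <- sum(sympt)
    inc_sympt[mi] <- inc_sympt[mi] + s
    diag_sympt <- diag_sympt + s
    diag_by_g <- diag_by_g + rowSums(sympt, dims = 1)

    # -- surveillance countdown: shift phases down; phase-2 mass is due now
    prec_due <- prec[, , 2]
    precl_due <- precl[, , 2]
    prec[, , 2:(n_phase - 1)] <- prec[, , 3:n_phase]; prec[, , n_phase] <- 0
    precl[, , 2:(n_phase - 1)] <- precl[, , 3:n_phase]; precl[, , n_phase] <- 0
    # -- routine screen (start of month), phase-1 (non-surveillance) mass only
    si <- which(screen_at == m)
    if (length(si) == 1L) {
      dmat <- det[[screen_mod[si]]]
      d <- dmat$prec
      detected <- prec[, , 1] * d
      prec[, , 1] <- prec[, , 1] - detected
      healthy <- healthy + sum(detected) * treat
      prec[, , n_phase] <- prec[, , n_phase] + detected * (1 - treat)
      d <- dmat$precl
      found <- precl[, , 1] * d
      precl[, , 1] <- precl[, , 1] - found
      inc_screen[mi] <- inc_screen[mi] + sum(found)
      diag_screen <- diag_screen + sum(found)
      diag_by_g <- diag_by_g + rowSums(found)
    }

    # -- surveillance visits on due mass
    if (sum(prec_due) > 0) {
      cured <- prec_due * det_surv * treat
      healthy <- healthy + sum(cured)
      prec[, , n_phase] <- prec[, , n_phase] + prec_due - cured
    }
    if (sum(precl_due) > 0) {
      found <- precl_due * det_surv
      inc_screen[mi] <- inc_screen[mi] + sum(found)
      diag_screen <- diag_screen + sum(found)
      diag_by_g <- diag_by_g + rowSums(found)
      precl[, , n_phase] <- precl[, , n_phase] + precl_due - found
    }

    # -- competing events: death, then hysterectomy, then disease transitions
    pd <- mod$pd[mi]; ph <- mod$ph[mi]
    if (pd > 0) {
      alive <- healthy + sum(hpv) + sum(prec) + sum(precl)
      dead <- dead + alive * pd
      healthy <- healthy * (1 - pd); hpv <- hpv * (1 - pd)
      prec <- prec * (1 - pd); precl <- precl * (1 - pd)
    }
    if (ph > 0) {
      # benign hysterectomy only from states without invasive cancer
      hyst <- hyst + (healthy + sum(hpv) + sum(prec)) * ph
      healthy <- healthy * (1 - ph); hpv <- hpv * (1 - ph)
      prec <- prec * (1 - ph)
    }

    a16 <- acq16[mi]; aoth <- acq_oth[mi]
    new_inf <- healthy * c(a16, aoth)
    onset <- hpv * pi_g                      # new precancers, occult split below
    cleared <- sum(hpv * c_g)
    to_cancer <- prec * tau                  # phase and occult carried over
    regressed <- rowSums(prec * rho_g, dims = 1) # collapses occult and phase

    healthy <- healthy * (1 - a16 - aoth) + cleared
    hpv <- hpv * (1 - pi_g - c_g) + new_inf + regressed
    prec <- prec * (1 - tau - rho_g)
    prec[, 1, 1] <- prec[, 1, 1] + onset * (1 - occ)
    prec[, 2, 1] <- prec[, 2, 1] + onset * occ
    precl <- precl + to_cancer
  }

  if (start_month > 0L) {
    # static pre-initialization history so occupancy rows always sum to one
    pre <- seq_len(start_month)
    eligible_start[pre] <- 1
    occupancy[pre, ] <- matrix(occupancy[start_month + 1L, ],
                               start_month, length(occ_names), byrow = TRUE)
  }

  list(
    by_month = tibble::tibble(
      month = seq_len(n_months) - 1L,
      eligible_start = eligible_start,
      inc_screen = inc_screen,
      inc_sympt = inc_sympt
    ),
    occupancy = dplyr::bind_cols(
      tibble::tibble(month = seq_len(n_months) - 1L),
      tibble::as_tibble(occupancy)
    ),
    lifetime_risk = 100 * (diag_screen + diag_sympt),
    diagnosed_by_genotype = diag_by_g
  )
}

#' @export
print.cohort_solution <- function(x, ...) {
  cat("<cohort_solution> variant:", x$variant %||% "?", "\n")
  cat(sprintf("  lifetime risk: %.4f%%\n", x$lifetime_risk))
  cat(sprintf("  expected diagnosed per 100,000: %.1f (screen-detected %.1f, symptomatic %.1f)\n",
              1e5 * x$lifetime_risk / 100,
              1e5 * sum(x$by_month$inc_screen),
              1e5 * sum(x$by_month$inc_sympt)))
  invisible(x)
}

#' Tidy monthly output of a cohort solution
#'
#' @param x A `cohort_solution`.
#' @param ... Unused.
#' @return The monthly tibble of eligible mass and incident cancer mass.
#' @export
tidy.cohort_solution <- function(x, ...) x$by_month

#' One-row summary of a cohort solution
#'
#' @param x A `cohort_solution`.
#' @param ... Unused.
#' @return A one-row tibble with lifetime risk and expected case counts.
#' @export
glance.cohort_solution <- function(x, ...) {
  tibble::tibble(
    variant = x$variant %||% NA_character_,
    lifetime_risk_pct = x$lifetime_risk,
    screen_detected_per_100k = 1e5 * sum(x$by_month$inc_screen),
    symptomatic_per_100k = 1e5 * sum(x$by_month$inc_sympt),
    hpv16_18_share = unname(
      x$diagnosed_by_genotype[1] / max(sum(x$diagnosed_by_genotype), .Machine$double.eps)
    )
  )
}
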