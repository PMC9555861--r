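genotype_levels <- function() c("hpv16_18", "other_hr")

#' Specification of a stylized natural-history variant
#'
#' The three shipped variants differ only in the mean dwell time from HPV
#' acquisition to symptomatic cancer (conditional on progression) and in
#' whether a fraction of precancers is persistently undetectable by cytology
#' ("occult" lesions, a feature of the short-dwell variant). Dwell targets
#' are stylized stand-ins chosen for strict ordering, not calibrated values.
#'
#' @param name One of `"short_dwell"`, `"medium_dwell"`, `"long_dwell"`.
#' @param dwell_target_years Target mean total dwell (years).
#' @param occult_fraction Probability a newly formed precancer is
#'   cytology-occult; must be in `[0, 0.2]`.
#' @return A list of class `variant_spec`.
#' @export
variant_spec <- function(name, dwell_target_years, occult_fraction = 0) {
  stopifnot(dwell_target_years > 0,
            occult_fraction >= 0, occult_fraction <= 0.2)
  structure(
    list(name = name, dwell_target_years = dwell_target_years,
         occult_fraction = occult_fraction),
    class = "variant_spec"
  )
}

builtin_variants <- function() {
  list(
    short_dwell = variant_spec("short_dwell", 10, occult_fraction = 0.10),
    medium_dwell = variant_spec("medium_dwell", 15, occult_fraction = 0),
    long_dwell = variant_spec("long_dwell", 20, occult_fraction = 0)
  )
}

# fraction of total dwell spent in each stage, and disease-progression splits;
# one fixed stylization shared by all variants so variants differ in rates only
dwell_stage_split <- c(hpv = 0.15, precancer = 0.50, preclinical = 0.35)
progression_given_infection <- c(hpv16_18 = 0.18, other_hr = 0.045)
cancer_given_precancer <- 0.32
acquisition_share_16_18 <- 0.25

base_acquisition_shape <- function(ages = 0:84) {
  x <- ages - 12
  f <- ifelse(ages >= 12 & ages < 65, stats::dgamma(x, shape = 3, scale = 5), 0)
  f / stats::dgamma(10, shape = 3, scale = 5) # peak (age 22) scaled to 1
}

#' Construct a natural-history parameter set
#'
#' Low-level constructor; most users call [make_variant()]. All transition
#' parameters are monthly probabilities (the model cycle is one month).
#'
#' @param variant_name Label for the parameter set.
#' @param hpv_incidence Tibble with columns `age` (0–84) and one column of
#'   monthly acquisition probabilities per genotype group (`hpv16_18`,
#'   `other_hr`).
#' @param clearance,progression_to_precancer,regression_from_precancer Named
#'   per-genotype monthly probabilities.
#' @param progression_to_cancer Monthly probability a precancer becomes
#'   preclinical invasive cancer.
#' @param symptomatic_detection_rate Monthly probability a preclinical cancer
#'   presents symptomatically.
#' @param occult_fraction Probability a new precancer is cytology-occult.
#' @param cyto_sens_precancer,cyto_sens_cancer,cyto_spec Cytology test
#'   characteristics.
#' @param hpv_sens,hpv_spec HPV test characteristics (used for both primary
#'   HPV testing and reflex/triage testing).
#' @param colposcopy_sens Colposcopy sensitivity for prevalent lesions.
#' @param colposcopy_compliance,treatment_compliance Attendance probabilities
#'   of the management cascade.
#' @param vaccine_efficacy_16_18 Default per-woman efficacy against HPV16/18
#'   acquisition (overridable per cohort via [make_vaccination_profile()]).
#' @param metadata Free-form provenance list.
#' @return A validated list of class `nh_params`.
#' @export
nh_params <- function(variant_name,
                      hpv_incidence,
                      clearance,
                      progression_to_precancer,
                      regression_from_precancer,
                      progression_to_cancer,
                      symptomatic_detection_rate,
                      occult_fraction,
                      cyto_sens_precancer = 0.55,
                      cyto_sens_cancer = 0.80,
                      cyto_spec = 0.97,
                      hpv_sens = 0.90,
                      hpv_spec = 0.94,
                      colposcopy_sens = 0.95,
                      colposcopy_compliance = 0.79,
                      treatment_compliance = 0.73,
                      vaccine_efficacy_16_18 = 0.95,
                      metadata = list()) {
  out <- structure(
    list(
      variant_name = variant_name,
      cycle_length = "month",
      hpv_incidence = tibble::as_tibble(hpv_incidence),
      clearance = clearance[genotype_levels()],
      progression_to_precancer = progression_to_precancer[genotype_levels()],
      regression_from_precancer = regression_from_precancer[genotype_levels()],
      progression_to_cancer = progression_to_cancer,
      symptomatic_detection_rate = symptomatic_detection_rate,
      occult_fraction = occult_fraction,
      cyto_sens_precancer = cyto_sens_precancer,
      cyto_sens_cancer = cyto_sens_cancer,
      cyto_spec = cyto_spec,
      hpv_sens = hpv_sens,
      hpv_spec = hpv_spec,
      colposcopy_sens = colposcopy_sens,
      colposcopy_compliance = colposcopy_compliance,
      treatment_compliance = treatment_compliance,
      vaccine_efficacy_16_18 = vaccine_efficacy_16_18,
      metadata = metadata
    ),
    class = "nh_params"
  )
  validate_params(out)
  out
}

#' Validate a natural-history parameter set
#'
#' Checks that all probabilities lie in `[0, 1]`, the incidence table covers
#' ages 0–84, and every per-cycle competing-event block is stochastic
#' (probabilities summing to at most 1).
#'
#' @param params An `nh_params` object.
#' @return `params`, invisibly; errors on violation.
#' @export
validate_params <- function(params) {
  p01 <- function(x, what) {
    if (anyNA(x) || any(x < 0) || any(x > 1)) {
      stop("parameter out of [0, 1]: ", what, call. = FALSE)
    }
  }
  inc <- params$hpv_incidence
  if (!identical(sort(inc$age), 0:84)) {
    stop("hpv_incidence must be indexed by ages 0-84", call. = FALSE)
  }
  for (g in genotype_levels()) p01(inc[[g]], paste0("hpv_incidence$", g))
  p01(params$clearance, "clearance")
  p01(params$progression_to_precancer, "progression_to_precancer")
  p01(params$regression_from_precancer, "regression_from_precancer")
  p01(params$progression_to_cancer, "progression_to_cancer")
  p01(params$symptomatic_detection_rate, "symptomatic_detection_rate")
  p01(params$occult_fraction, "occult_fraction")
  for (f in c("cyto_sens_precancer", "cyto_sens_cancer", "cyto_spec",
              "hpv_sens", "hpv_spec", "colposcopy_sens",
              "colposcopy_compliance", "treatment_compliance",
              "vaccine_efficacy_16_18")) {
    p01(params[[f]], f)
  }
  if (any(inc$hpv16_18 + inc$other_hr > 1)) {
    stop("combined monthly acquisition probability exceeds 1", call. = FALSE)
  }
  if (any(params$clearance + params$progression_to_precancer > 1)) {
    stop("HPV-state exit probabilities exceed 1 in a cycle", call. = FALSE)
  }
  if (any(params$regression_from_precancer + params$progression_to_cancer > 1)) {
    stop("precancer-state exit probabilities exceed 1 in a cycle", call. = FALSE)
  }
  invisible(params)
}

#' Mean stage sojourn times implied by a parameter set
#'
#' For geometric sojourns the mean time in a state is `1 / (total monthly
#' exit probability)` months, independent of which exit is taken; a stage
#' with zero exit probability is reported as an infinite sojourn.
#'
#' @param params An `nh_params` object.
#' @return A tibble with one row per genotype and stage
#'   (`hpv_to_precancer`, `precancer_to_preclinical`,
#'   `preclinical_to_symptomatic`) and the mean sojourn in months.
#' @export
#' @examples
#' dwell_time_summary(make_variant("short_dwell", calibrate = FALSE))
dwell_time_summary <- function(params) {
  g <- genotype_levels()
  exit_hpv <- params$clearance[g] + params$progression_to_precancer[g]
  exit_prec <- params$regression_from_precancer[g] + params$progression_to_cancer
  exit_precl <- rep(params$symptomatic_detection_rate, 2)
  tibble::tibble(
    genotype = rep(g, 3),
    stage = rep(c("hpv_to_precancer", "precancer_to_preclinical",
                  "preclinical_to_symptomatic"), each = 2),
    mean_months = unname(c(1 / exit_hpv, 1 / exit_prec, 1 / exit_precl))
  )
}

#' Total mean dwell time (acquisition to symptomatic cancer) in years
#'
#' @param params An `nh_params` object.
#' @return Named numeric, one total per genotype group.
#' @export
total_dwell_years <- function(params) {
  d <- dwell_time_summary(params)
  out <- tapply(d$mean_months, d$genotype, sum) / 12
  out[genotype_levels()]
}

#' Generate a complete natural-history parameter set for one variant
#'
#' Transition probabilities are derived analytically from the variant's dwell
#' target (so [dwell_time_summary()] reproduces the target exactly), and the
#' HPV acquisition amplitude is then scaled by a short deterministic
#' fixed-point iteration until the no-screening lifetime risk under the
#' default demography hits `target_lifetime_risk` (a light self-calibration;
#' no registry fitting is attempted). The result is deterministic for a given
#' seed and configuration.
#'
#' @param variant A variant name (`"short_dwell"`, `"medium_dwell"`,
#'   `"long_dwell"`) or a [variant_spec()].
#' @param seed Integer; retained in the metadata and for interface stability
#'   (generation itself is deterministic).
#' @param calibrate If `TRUE` (default), run the lifetime-risk scaling.
#' @param demography Demography used during calibration.
#' @param target_lifetime_risk No-screening lifetime risk (percent) aimed for
#'   during calibration; must produce a value in the plausible 0.5–2 percent
#'   band or generation errors.
#' @param base_amplitude Peak monthly acquisition probability before scaling.
#' @return An `nh_params` object.
#' @export
#' @examples
#' p <- make_variant("medium_dwell", calibrate = FALSE)
#' total_dwell_years(p)
make_variant <- function(variant, seed = 1L, calibrate = TRUE,
                         demography = make_demography(),
                         target_lifetime_risk = 1.0,
                         base_amplitude = 0.002) {
  spec <- if (inherits(variant, "variant_spec")) variant else {
    v <- builtin_variants()[[match.arg(variant, names(builtin_variants()))]]
    v
  }
  t_tot <- spec$dwell_target_years * 12
  t_stage <- dwell_stage_split * t_tot
  exit_hpv <- 1 / t_stage[["hpv"]]
  exit_prec <- 1 / t_stage[["precancer"]]
  sigma <- 1 / t_stage[["preclinical"]]
  pi_g <- progression_given_infection * exit_hpv
  c_g <- exit_hpv - pi_g
  tau <- cancer_given_precancer * exit_prec
  rho_g <- stats::setNames(rep(exit_prec - tau, 2), genotype_levels())

  shape <- base_acquisition_shape()
  build <- function(amplitude) {
    nh_params(
      variant_name = spec$name,
      hpv_incidence = tibble::tibble(
        age = 0:84,
        hpv16_18 = amplitude * shape * acquisition_share_16_18,
        other_hr = amplitude * shape * (1 - acquisition_share_16_18)
      ),
      clearance = c_g,
      progression_to_precancer = pi_g,
      regression_from_precancer = rho_g,
      progression_to_cancer = tau,
      symptomatic_detection_rate = sigma,
      occult_fraction = spec$occult_fraction,
      metadata = list(
        dwell_target_years = spec$dwell_target_years,
        stylized = TRUE,
        seed = as.integer(seed),
        acquisition_amplitude = amplitude,
        calibrated = calibrate,
        target_lifetime_risk = if (calibrate) target_lifetime_risk else NA_real_
      )
    )
  }

  amplitude <- base_amplitude
  params <- build(amplitude)
  if (calibrate) {
    no_screen <- empty_schedule(1975L)
    for (i in 1:4) {
      sol <- cohort_solve(no_screen, params, demography,
                          make_vaccination_profile(1975L, coverage = 0))
      risk <- lifetime_risk(sol)
      if (risk <= 0) {
        stop("calibration failed: degenerate (zero-risk) epidemic for variant ",
             spec$name, call. = FALSE)
      }
      amplitude <- amplitude * target_lifetime_risk / risk
      params <- build(amplitude)
    }
    sol <- cohort_solve(no_screen, params, demography,
                        make_vaccination_profile(1975L, coverage = 0))
    risk <- lifetime_risk(sol)
    if (risk < 0.5 || risk > 2) {
      stop(sprintf(
        "calibration failed for variant %s: no-screening lifetime risk %.3f%% outside 0.5-2%%",
        spec$name, risk), call. = FALSE)
    }
    params$metadata$achieved_lifetime_risk <- risk
  }
  params
}

#' @export
print.nh_params <- function(x, ...) {
  cat("<nh_params> variant:", x$variant_name, "\n")
  d <- total_dwell_years(x)
  cat(sprintf("  mean dwell (years): hpv16_18 %.1f, other_hr %.1f\n",
              d[["hpv16_18"]], d[["other_hr"]]))
  cat(sprintf("  occult fraction: %.2f | cyto sens (precancer) %.2f | hpv sens %.2f\n",
              x$occult_fraction, x$cyto_sens_precancer, x$hpv_sens))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the transition parameters of a natural-history variant
#'
#' @param x An `nh_params` object.
#' @param ... Unused.
#' @return A tibble with one row per genotype-specific monthly transition
#'   probability.
#' @export
tidy.nh_params <- function(x, ...) {
  g <- genotype_levels()
  tibble::tibble(
    genotype = rep(g, 4),
    transition = rep(c("clearance", "progression_to_precancer",
                       "regression_from_precancer", "progression_to_cancer"),
                     each = 2),
    monthly_probability = c(
      x$clearance[g], x$progression_to_precancer[g],
      x$regression_from_precancer[g],
      rep(x$progression_to_cancer, 2)
    )
  )
}

#' One-row summary of a natural-history variant
#'
#' @param x An `nh_params` object.
#' @param ... Unused.
#' @return A one-row tibble with dwell totals and test characteristics.
#' @export
glance.nh_params <- function(x, ...) {
  d <- total_dwell_years(x)
  tibble::tibble(
    variant = x$variant_name,
    dwell_years_hpv16_18 = d[["hpv16_18"]],
    dwell_years_other_hr = d[["other_hr"]],
    occult_fraction = x$occult_fraction,
    cyto_sens_precancer = x$cyto_sens_precancer,
    hpv_sens = x$hpv_sens,
    colposcopy_compliance = x$colposcopy_compliance,
    treatment_compliance = x$treatment_compliance
  )
}
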