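# Shared fixtures, built in code. Calibrated variants are cached per session
# because calibration re-runs the cohort solver.

.fixture_cache <- new.env(parent = emptyenv())

test_variant <- function(variant = "short_dwell") {
  key <- paste0("v_", variant)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_variant(variant, seed = 1L)
  }
  .fixture_cache[[key]]
}

test_demography <- function() {
  if (is.null(.fixture_cache$dem)) .fixture_cache$dem <- make_demography()
  .fixture_cache$dem
}

unvaccinated <- function(birth_year = 1975L) {
  make_vaccination_profile(birth_year, coverage = 0)
}

# a parameter set with every hazard switched off, for no-event identities
null_params <- function(...) {
  base <- make_variant("medium_dwell", calibrate = FALSE)
  zero2 <- c(hpv16_18 = 0, other_hr = 0)
  mods <- list(
    hpv_incidence = tibble::tibble(age = 0:84, hpv16_18 = 0, other_hr = 0),
    clearance = zero2,
    progression_to_precancer = zero2,
    regression_from_precancer = zero2,
    progression_to_cancer = 0,
    symptomatic_detection_rate = 0,
    occult_fraction = 0
  )
  overrides <- list(...)
  for (nm in names(overrides)) mods[[nm]] <- overrides[[nm]]
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  validate_params(base)
  base
}

# binomial three-sigma band check
within_3se <- function(observed, expected_p, n) {
  se <- sqrt(expected_p * (1 - expected_p) / n)
  abs(observed - expected_p) <= 3 * se
}
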