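#' Synthetic demography: other-cause mortality and benign hysterectomy
#'
#' Builds the age-indexed monthly probability tables the simulator consumes:
#' a smooth Gompertz-plus-background other-cause death hazard (monotone
#' non-decreasing in age) and a unimodal mid-life benign-hysterectomy hazard.
#' The defaults give survival to age 84 of about 0.79 and a lifetime
#' hysterectomy fraction of about 0.26 — stylized US-like values, not a fitted
#' life table.
#'
#' @param seed Unused (generation is deterministic); retained for interface
#'   symmetry with the other generators.
#' @param background Annual background death hazard.
#' @param gompertz_rate,gompertz_scale Gompertz shape/level of the senescent
#'   death hazard.
#' @param hyst_lifetime Total lifetime hysterectomy hazard (area under the
#'   annual hazard curve).
#' @param hyst_peak_age,hyst_sd Location and width of the hysterectomy hazard.
#' @return A tibble of class `demography` with columns `age` (0–84),
#'   `p_death_month`, `p_hyst_month`.
#' @export
#' @examples
#' dem <- make_demography()
#' survival_to_84(dem)
make_demography <- function(seed = NULL,
                            background = 5e-4,
                            gompertz_rate = 0.095,
                            gompertz_scale = 6.7e-6,
                            hyst_lifetime = 0.30,
                            hyst_peak_age = 45,
                            hyst_sd = 9) {
  age <- 0:84
  h_death <- background + gompertz_scale * exp(gompertz_rate * age)
  h_hyst <- ifelse(age >= 18, hyst_lifetime * stats::dnorm(age, hyst_peak_age, hyst_sd), 0)
  out <- tibble::tibble(
    age = age,
    p_death_month = 1 - exp(-h_death / 12),
    p_hyst_month = 1 - exp(-h_hyst / 12)
  )
  class(out) <- c("demography", class(out))
  out
}

#' Zero-hazard demography (no competing risks)
#'
#' Convenience for analytic verification settings where every woman reaches
#' age 84.
#'
#' @return A `demography` tibble of zeros.
#' @export
zero_demography <- function() {
  out <- tibble::tibble(age = 0:84, p_death_month = 0, p_hyst_month = 0)
  class(out) <- c("demography", class(out))
  out
}

validate_demography <- function(demography) {
  stopifnot(identical(demography$age, 0:84))
  for (col in c("p_death_month", "p_hyst_month")) {
    x <- demography[[col]]
    if (anyNA(x) || any(x < 0) || any(x > 1)) {
      stop("demography probabilities out of [0, 1]: ", col, call. = FALSE)
    }
  }
  invisible(demography)
}

#' Product-limit survival to age 84 implied by a demography table
#'
#' @param demography A [make_demography()] tibble.
#' @return Probability of surviving other-cause death from birth to age 84.
#' @export
survival_to_84 <- function(demography) {
  prod((1 - demography$p_death_month)^12)
}

#' Write / read a demography table as CSV
#'
#' @param demography A `demography` tibble.
#' @param path File path.
#' @return `path` (write) or the `demography` tibble (read).
#' @export
write_demography <- function(demography, path) {
  validate_demography(demography)
  utils::write.csv(as.data.frame(demography), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_demography
#' @export
read_demography <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  out$age <- as.integer(out$age)
  class(out) <- c("demography", class(out))
  validate_demography(out)
  out
}

#' Birth-cohort HPV vaccination profile
#'
#' Defaults mirror the historical pattern of the default grid: the 1965 and
#' 1975 cohorts predate routine HPV vaccination (coverage 0) while the 1985
#' cohort carries configurable catch-up coverage. Vaccinated women have their
#' HPV16/18 acquisition probability multiplied by `1 - efficacy_16_18`.
#'
#' @param birth_year Cohort birth year.
#' @param coverage Fraction vaccinated; `NULL` picks the cohort default
#'   (0 / 0 / 0.35 for 1965 / 1975 / 1985, 0 otherwise).
#' @param efficacy_16_18 Per-woman efficacy against HPV16/18 acquisition.
#' @return A one-row tibble of class `vaccination_profile`.
#' @export
#' @examples
#' make_vaccination_profile(1985)
make_vaccination_profile <- function(birth_year, coverage = NULL,
                                     efficacy_16_18 = 0.95) {
  if (is.null(coverage)) {
    defaults <- c(`1965` = 0, `1975` = 0, `1985` = 0.35)
    coverage <- unname(defaults[as.character(birth_year)])
    if (is.na(coverage)) coverage <- 0
  }
  stopifnot(coverage >= 0, coverage <= 1,
            efficacy_16_18 >= 0, efficacy_16_18 <= 1)
  out <- tibble::tibble(
    birth_year = as.integer(birth_year),
    coverage = coverage,
    efficacy_16_18 = efficacy_16_18
  )
  class(out) <- c("vaccination_profile", class(out))
  out
}
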