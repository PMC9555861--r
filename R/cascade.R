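state_levels <- function() {
  c("HEALTHY", "HPV_INFECTED", "PRECANCER", "PRECLINICAL_CANCER",
    "DIAGNOSED_CANCER", "HYSTERECTOMY", "DEAD_OTHER")
}
absorbing_states <- function() c("DIAGNOSED_CANCER", "HYSTERECTOMY", "DEAD_OTHER")
genotype_labels <- function() c("HPV16_18", "OTHER_HR", "NONE")

#' Construct a validated table of health states
#'
#' @param label Health-state labels (see `Details`).
#' @param genotype `"HPV16_18"`, `"OTHER_HR"`, or `"NONE"`.
#' @param occult Logical; lesion persistently undetectable by cytology. Only
#'   meaningful for precancer / preclinical-cancer states.
#' @details States: `HEALTHY`, `HPV_INFECTED`, `PRECANCER` (CIN2/3 merged),
#'   `PRECLINICAL_CANCER`, `DIAGNOSED_CANCER`, `HYSTERECTOMY`, `DEAD_OTHER`.
#'   Genotype is `NONE` exactly in the states without an HPV-driven lesion or
#'   infection, and the occult flag may be set only for lesion states.
#' @return A tibble with columns `label`, `genotype`, `occult`.
#' @export
#' @examples
#' health_states("HPV_INFECTED", "HPV16_18")
health_states <- function(label, genotype = "NONE", occult = FALSE) {
  out <- tibble::tibble(label = label, genotype = genotype, occult = occult)
  stopifnot(all(out$label %in% state_levels()),
            all(out$genotype %in% genotype_labels()))
  no_geno <- out$label %in% c("HEALTHY", "HYSTERECTOMY", "DEAD_OTHER")
  if (any(no_geno != (out$genotype == "NONE"))) {
    stop("genotype must be NONE exactly for states without HPV involvement",
         call. = FALSE)
  }
  if (any(out$occult & !out$label %in% c("PRECANCER", "PRECLINICAL_CANCER"))) {
    stop("occult flag is only defined for lesion states", call. = FALSE)
  }
  out
}

state_stage <- function(label) {
  dplyr::case_match(label,
    "HEALTHY" ~ "healthy",
    "HPV_INFECTED" ~ "hpv",
    "PRECANCER" ~ "prec",
    "PRECLINICAL_CANCER" ~ "precl",
    .default = NA_character_
  )
}

cyto_positive_prob <- function(stage, occult, params) {
  p <- rep(1 - params$cyto_spec, length(stage))
  p[stage == "prec"] <- ifelse(occult[stage == "prec"], 0, params$cyto_sens_precancer)
  p[stage == "precl"] <- ifelse(occult[stage == "precl"], 0, params$cyto_sens_cancer)
  p
}

#' Apply one routine primary screen to a table of women
#'
#' Vectorized over rows. Primary cytology is positive (ASCUS or worse) with
#' the state-specific sensitivity — zero for cytology-occult lesions — or with
#' `1 - cyto_spec` in lesion-free states; positives receive reflex HPV
#' testing, and only reflex-positive women are referred to colposcopy. Primary
#' HPV testing is positive with `hpv_sens` whenever HPV involvement is present
#' (analytic false positives use `1 - hpv_spec` and are genotyped as other
#' high-risk); HPV16/18 calls are referred directly while other high-risk
#' calls require ASCUS+ triage cytology.
#'
#' @param data A [health_states()] tibble of screen-eligible women.
#' @param modality `"CYTOLOGY"` or `"HPV_PRIMARY"`.
#' @param params An `nh_params` object.
#' @return `data` with columns `modality`, `result`, `genotype_call`,
#'   `triage_cytology_result`, `referred_to_colposcopy` appended.
#' @export
#' @examples
#' set.seed(1)
#' women <- health_states(rep("PRECANCER", 5), "HPV16_18")
#' perform_screen(women, "HPV_PRIMARY", make_variant("short_dwell", calibrate = FALSE))
perform_screen <- function(data, modality, params) {
  modality <- match.arg(modality, scenario_modalities())
  if (any(data$label %in% absorbing_states())) {
    stop("perform_screen called on an ineligible (absorbing) state", call. = FALSE)
  }
  n <- nrow(data)
  stage <- state_stage(data$label)
  hpv_pos_p <- ifelse(stage == "healthy", 1 - params$hpv_spec, params$hpv_sens)
  cyto_pos_p <- cyto_positive_prob(stage, data$occult, params)

  if (modality == "CYTOLOGY") {
    result <- stats::runif(n) < cyto_pos_p
    referred <- result & (stats::runif(n) < hpv_pos_p)
    call <- rep("NONE", n)
    triage <- rep(NA_character_, n)
  } else {
    result <- stats::runif(n) < hpv_pos_p
    call <- dplyr::if_else(result,
                           dplyr::if_else(stage == "healthy", "OTHER_HR", data$genotype),
                           "NONE")
    need_triage <- result & call == "OTHER_HR"
    triage_pos <- need_triage & (stats::runif(n) < cyto_pos_p)
    triage <- dplyr::case_when(
      triage_pos ~ "ASCUS_PLUS",
      need_triage ~ "NEGATIVE",
      .default = NA_character_
    )
    referred <- (result & call == "HPV16_18") | triage_pos
  }
  dplyr::mutate(
    data,
    modality = modality,
    result = dplyr::if_else(result, "POSITIVE", "NEGATIVE"),
    genotype_call = call,
    triage_cytology_result = triage,
    referred_to_colposcopy = referred
  )
}

#' Manage colposcopy referrals
#'
#' Vectorized over rows: referred women attend colposcopy with the compliance
#' probability; attended colposcopies detect a prevalent precancer or
#' preclinical cancer with `colposcopy_sens`; detected precancers are treated
#' (returning the woman to `HEALTHY` with the causal infection cleared) with
#' the treatment-compliance probability, and detected-but-untreated lesions
#' enter annual surveillance re-management; a detected preclinical cancer is
#' diagnosed as screen-detected.
#'
#' @param data Output rows of [perform_screen()] with
#'   `referred_to_colposcopy = TRUE` (error otherwise).
#' @param params An `nh_params` object.
#' @return `data` with management columns `attended_colposcopy`,
#'   `lesion_detected`, `treated`, `cancer_screen_detected`, the updated state
#'   in `new_label` / `new_genotype` / `new_occult`, and
#'   `surveillance_in_months` (`12` for detected-untreated lesions, `NA`
#'   otherwise).
#' @export
manage_positive <- function(data, params) {
  if (!all(data$referred_to_colposcopy)) {
    stop("manage_positive called on a non-referred screen outcome", call. = FALSE)
  }
  n <- nrow(data)
  attended <- stats::runif(n) < params$colposcopy_compliance
  lesion_present <- data$label %in% c("PRECANCER", "PRECLINICAL_CANCER")
  detected <- attended & lesion_present & (stats::runif(n) < params$colposcopy_sens)
  is_prec <- data$label == "PRECANCER"
  treated <- detected & is_prec & (stats::runif(n) < params$treatment_compliance)
  cancer_found <- detected & data$label == "PRECLINICAL_CANCER"

  dplyr::mutate(
    data,
    attended_colposcopy = attended,
    lesion_detected = detected,
    treated = treated,
    cancer_screen_detected = cancer_found,
    new_label = dplyr::case_when(
      treated ~ "HEALTHY",
      cancer_found ~ "DIAGNOSED_CANCER",
      .default = data$label
    ),
    new_genotype = dplyr::if_else(treated, "NONE", data$genotype),
    new_occult = dplyr::if_else(treated, FALSE, data$occult),
    surveillance_in_months = dplyr::if_else(detected & is_prec & !treated,
                                            12L, NA_integer_)
  )
}

#' One natural-history cycle for a table of women
#'
#' Applies a single monthly competing-event update (no screening):
#' symptomatic presentation of a preclinical cancer resolves at the start of
#' the cycle, then death, then benign hysterectomy, then at most one further
#' disease transition, in that fixed priority. A new precancer is flagged
#' cytology-occult with probability `occult_fraction` at onset, and the flag
#' is never reassigned while the lesion persists.
#'
#' @param data A [health_states()] tibble; absorbing input states are a
#'   contract violation.
#' @param age Age in months (single value applied to all rows).
#' @param params An `nh_params` object.
#' @param demography A [make_demography()] tibble.
#' @return A tibble of next-cycle states (`label`, `genotype`, `occult`).
#' @export
#' @examples
#' set.seed(1)
#' p <- make_variant("short_dwell", calibrate = FALSE)
#' nh_step(health_states(rep("HPV_INFECTED", 4), "OTHER_HR"), 300, p, make_demography())
nh_step <- function(data, age, params, demography) {
  if (any(data$label %in% absorbing_states())) {
    stop("nh_step called on an absorbing state", call. = FALSE)
  }
  stopifnot(age >= 0, age < 84 * 12)
  n <- nrow(data)
  year <- age %/% 12
  pd <- demography$p_death_month[demography$age == year]
  ph <- demography$p_hyst_month[demography$age == year]
  a16 <- params$hpv_incidence$hpv16_18[params$hpv_incidence$age == year]
  aoth <- params$hpv_incidence$other_hr[params$hpv_incidence$age == year]

  sympt <- data$label == "PRECLINICAL_CANCER" &
    stats::runif(n) < params$symptomatic_detection_rate
  dies <- !sympt & stats::runif(n) < pd
  hyst <- !sympt & !dies & data$label != "PRECLINICAL_CANCER" & (stats::runif(n) < ph)

  u <- stats::runif(n)
  g <- tolower(data$genotype)
  pi_g <- unname(params$progression_to_precancer[g])
  c_g <- unname(params$clearance[g])
  rho_g <- unname(params$regression_from_precancer[g])
  tau <- params$progression_to_cancer

  label <- data$label; genotype <- data$genotype; occult <- data$occult
  free <- !sympt & !dies & !hyst

  i <- free & label == "HEALTHY"
  acq16 <- i & u < a16
  acqoth <- i & u >= a16 & u < a16 + aoth
  label[acq16 | acqoth] <- "HPV_INFECTED"
  genotype[acq16] <- "HPV16_18"; genotype[acqoth] <- "OTHER_HR"

  i <- free & data$label == "HPV_INFECTED"
  prog <- i & u < pi_g
  clear <- i & !prog & u < pi_g + c_g
  label[prog] <- "PRECANCER"
  occult[prog] <- stats::runif(sum(prog)) < params$occult_fraction
  label[clear] <- "HEALTHY"; genotype[clear] <- "NONE"

  i <- free & data$label == "PRECANCER"
  to_cancer <- i & u < tau
  regress <- i & !to_cancer & u < tau + rho_g
  label[to_cancer] <- "PRECLINICAL_CANCER"
  label[regress] <- "HPV_INFECTED"; occult[regress] <- FALSE

  label[sympt] <- "DIAGNOSED_CANCER"

  label[dies] <- "DEAD_OTHER"
  label[hyst] <- "HYSTERECTOMY"
  genotype[dies | hyst] <- "NONE"
  occult[dies | hyst] <- FALSE

  tibble::tibble(label = label, genotype = genotype, occult = occult)
}
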