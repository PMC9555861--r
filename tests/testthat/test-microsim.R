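allowed_edges <- function() {
  list(
    HEALTHY = c("HPV_INFECTED", "HYSTERECTOMY", "DEAD_OTHER"),
    HPV_INFECTED = c("HEALTHY", "PRECANCER", "HYSTERECTOMY", "DEAD_OTHER"),
    PRECANCER = c("HEALTHY", "HPV_INFECTED", "PRECLINICAL_CANCER",
                  "HYSTERECTOMY", "DEAD_OTHER"),
    PRECLINICAL_CANCER = c("DIAGNOSED_CANCER", "DEAD_OTHER")
  )
}

test_that("identical seeds reproduce identical trajectories bitwise", {
  p <- test_variant("short_dwell")
  sch <- build_schedule(scenario_spec(1975, 3, "CYTOLOGY", 1))
  a <- simulate_life_course(sch, p, test_demography(), unvaccinated(), seed = 31, n = 200)
  b <- simulate_life_course(sch, p, test_demography(), unvaccinated(), seed = 31, n = 200)
  expect_identical(a$events, b$events)
  expect_identical(a$screens, b$screens)
  expect_identical(a$women, b$women)
})

test_that("sampled trajectories only use allowed transitions and absorb correctly", {
  p <- test_variant("short_dwell")
  sch <- build_schedule(scenario_spec(1985, 3, "HPV_PRIMARY", 2))
  lc <- simulate_life_course(sch, p, test_demography(),
                             make_vaccination_profile(1985), seed = 17, n = 3000)
  edges <- allowed_edges()
  bad <- 0L
  for (w in split(lc$events, lc$events$woman)) {
    s <- w$state
    if (length(s) > 1) {
      for (k in seq_len(length(s) - 1)) {
        if (!(s[k + 1] %in% edges[[s[k]]])) bad <- bad + 1L
      }
    }
    # absorbing states end the path
    if (any(s %in% c("DIAGNOSED_CANCER", "DEAD_OTHER", "HYSTERECTOMY"))) {
      expect_equal(which(s %in% c("DIAGNOSED_CANCER", "DEAD_OTHER", "HYSTERECTOMY")),
                   length(s))
    }
  }
  expect_equal(bad, 0L)
  # at most one diagnosis, present iff DIAGNOSED_CANCER reached
  n_diag <- tapply(lc$events$state == "DIAGNOSED_CANCER", lc$events$woman, sum)
  expect_true(all(n_diag <= 1))
  diagnosed_in_events <- names(n_diag)[n_diag == 1]
  diagnosed_in_summary <- as.character(lc$women$woman[lc$women$diag_mode != "NONE"])
  expect_setequal(diagnosed_in_events, diagnosed_in_summary)
})

test_that("occult lesions are never detected by any cytology screen", {
  p <- test_variant("short_dwell") # occult fraction 0.10
  sch <- build_schedule(scenario_spec(1975, 1, "CYTOLOGY", 0))
  lc <- simulate_life_course(sch, p, test_demography(), unvaccinated(),
                             seed = 23, n = 5000)
  occult_screens <- lc$screens[
    lc$screens$kind == "ROUTINE" & lc$screens$modality == "CYTOLOGY" &
      lc$screens$occult == 1 &
      lc$screens$state %in% c("PRECANCER", "PRECLINICAL_CANCER"), ]
  expect_gt(nrow(occult_screens), 0)
  expect_true(all(occult_screens$result == 0))
  expect_true(all(occult_screens$detected == 0))
})

test_that("screen-detected and symptomatic diagnoses respect the contact rules", {
  p <- test_variant("medium_dwell")
  sch <- build_schedule(scenario_spec(1965, 3, "CYTOLOGY", 0))
  lc <- simulate_life_course(sch, p, test_demography(), unvaccinated(),
                             seed = 29, n = 20000)
  w <- lc$women
  contacts <- paste(lc$screens$woman, lc$screens$month)
  screen_diag <- w[w$diag_mode == "SCREEN_DETECTED", ]
  expect_true(all(paste(screen_diag$woman, screen_diag$diag_month) %in% contacts))
  sympt <- w[w$diag_mode == "SYMPTOMATIC", ]
  expect_false(any(paste(sympt$woman, sympt$diag_month) %in% contacts))
})

test_that("zero progression to cancer means no diagnoses ever", {
  p <- test_variant("short_dwell")
  p$progression_to_cancer <- 0
  sim <- simulate_cohort(build_schedule(scenario_spec(1975, 3, "CYTOLOGY", 0)),
                         p, test_demography(), unvaccinated(), n = 5000, seed = 3)
  expect_true(all(sim$women$diag_mode == "NONE"))
})

test_that("common random numbers align histories before the disruption", {
  p <- test_variant("short_dwell")
  dem <- test_demography()
  lc0 <- simulate_life_course(build_schedule(scenario_spec(1975, 3, "CYTOLOGY", 0)),
                              p, dem, unvaccinated(), seed = 41, n = 400)
  lc5 <- simulate_life_course(build_schedule(scenario_spec(1975, 3, "CYTOLOGY", 5)),
                              p, dem, unvaccinated(), seed = 41, n = 400)
  cut <- (2020 - 1975) * 12
  pre <- function(lc) lc$events[lc$events$month < cut, ]
  expect_identical(pre(lc0), pre(lc5))
})

test_that("full-coverage full-efficacy vaccination eliminates HPV16/18 cancers", {
  p <- test_variant("short_dwell")
  sim <- simulate_cohort(empty_schedule(1985), p, test_demography(),
                         make_vaccination_profile(1985, coverage = 1, efficacy_16_18 = 1),
                         n = 50000, seed = 13)
  diag <- sim$women[sim$women$diag_mode != "NONE", ]
  expect_gt(nrow(diag), 0)
  expect_true(all(diag$diag_genotype == "OTHER_HR"))
})

test_that("schedules violating eligibility or the horizon are rejected", {
  p <- test_variant("short_dwell")
  sch <- build_schedule(scenario_spec(1975, 3, "CYTOLOGY", 0))
  bad <- sch; bad$age_years[1] <- 15L; bad$month[1] <- 15L * 12L
  expect_error(
    simulate_cohort(bad, p, test_demography(), unvaccinated(), 10, 1),
    "eligibility"
  )
  bad <- sch; bad$month[nrow(bad)] <- 85L * 12L
  expect_error(
    simulate_cohort(bad, p, test_demography(), unvaccinated(), 10, 1),
    "age 84"
  )
})
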