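test_that("state-occupancy fractions sum to one at every age", {
  p <- test_variant("short_dwell")
  for (sch in list(empty_schedule(1975),
                   build_schedule(scenario_spec(1985, 3, "HPV_PRIMARY", 2)))) {
    sol <- cohort_solve(sch, p, test_demography(),
                        make_vaccination_profile(attr(sch, "birth_year")))
    sums <- rowSums(as.matrix(sol$occupancy[-1]))
    expect_lt(max(abs(sums - 1)), 1e-10)
  }
})

test_that("zero-hazard parameters give exactly zero lifetime risk", {
  sol <- cohort_solve(empty_schedule(1975), null_params(), test_demography(),
                      unvaccinated())
  expect_identical(sol$lifetime_risk, 0)
})

test_that("constant-hazard configuration reproduces the exponential closed form", {
  p <- null_params(symptomatic_detection_rate = 1 - exp(-0.001 / 12))
  sol <- cohort_solve(empty_schedule(1975), p, zero_demography(), unvaccinated(),
                      init = list(state = "PRECLINICAL_CANCER", month = 240))
  expect_equal(sol$lifetime_risk, 100 * (1 - exp(-0.064)), tolerance = 1e-12)
})

test_that("screening with zero test sensitivity equals no screening exactly", {
  p <- test_variant("medium_dwell")
  p$cyto_sens_precancer <- 0; p$cyto_sens_cancer <- 0
  p$hpv_sens <- 0; p$cyto_spec <- 1; p$hpv_spec <- 1
  dem <- test_demography()
  ref <- cohort_solve(empty_schedule(1975), p, dem, unvaccinated())
  scr <- cohort_solve(build_schedule(scenario_spec(1975, 1, "CYTOLOGY", 0)),
                      p, dem, unvaccinated())
  expect_equal(scr$lifetime_risk, ref$lifetime_risk, tolerance = 1e-12)
})

test_that("microsimulation agrees with the solver on small scenarios", {
  p <- test_variant("short_dwell")
  dem <- test_demography()
  for (spec in list(scenario_spec(1975, 3, "CYTOLOGY", 1),
                    scenario_spec(1985, 5, "HPV_PRIMARY", 2))) {
    sch <- build_schedule(spec)
    vac <- make_vaccination_profile(spec$birth_year)
    sol <- cohort_solve(sch, p, dem, vac)
    sim <- simulate_cohort(sch, p, dem, vac, n = 4e4, seed = 20220101)
    expect_true(within_3se(lifetime_risk(sim) / 100, sol$lifetime_risk / 100, 4e4))
  }
})

test_that("vaccination scales HPV16/18-attributed cancers linearly under full efficacy", {
  p <- test_variant("medium_dwell")
  p$vaccine_efficacy_16_18 <- 1
  dem <- test_demography()
  sch <- empty_schedule(1985)
  base <- cohort_solve(sch, p, dem, make_vaccination_profile(1985, coverage = 0, efficacy_16_18 = 1))
  mixed <- cohort_solve(sch, p, dem, make_vaccination_profile(1985, coverage = 0.4, efficacy_16_18 = 1))
  full <- cohort_solve(sch, p, dem, make_vaccination_profile(1985, coverage = 1, efficacy_16_18 = 1))
  expect_equal(mixed$diagnosed_by_genotype[["hpv16_18"]],
               0.6 * base$diagnosed_by_genotype[["hpv16_18"]], tolerance = 1e-9)
  expect_equal(full$diagnosed_by_genotype[["hpv16_18"]], 0)
  # blocking 16/18 leaves women susceptible longer, so other-HR cancers can
  # only move up (competing-exposure effect), and only slightly
  expect_gte(mixed$diagnosed_by_genotype[["other_hr"]],
             base$diagnosed_by_genotype[["other_hr"]])
  expect_lt(mixed$diagnosed_by_genotype[["other_hr"]] /
              base$diagnosed_by_genotype[["other_hr"]], 1.05)
})

test_that("zero-efficacy vaccination changes nothing", {
  p <- test_variant("short_dwell")
  dem <- test_demography()
  sch <- empty_schedule(1985)
  a <- cohort_solve(sch, p, dem, make_vaccination_profile(1985, coverage = 0))
  b <- cohort_solve(sch, p, dem, make_vaccination_profile(1985, coverage = 0.5, efficacy_16_18 = 0))
  expect_equal(a$lifetime_risk, b$lifetime_risk, tolerance = 1e-12)
})
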