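test_that("mean sojourns are the reciprocal of the monthly exit probability", {
  p <- null_params(progression_to_cancer = 0.01,
                   symptomatic_detection_rate = 0.02,
                   clearance = c(hpv16_18 = 0.04, other_hr = 0.04),
                   progression_to_precancer = c(hpv16_18 = 0.01, other_hr = 0.01))
  d <- dwell_time_summary(p)
  expect_equal(d$mean_months[d$stage == "precancer_to_preclinical"], c(100, 100))
  expect_equal(d$mean_months[d$stage == "hpv_to_precancer"], c(20, 20))
  expect_equal(d$mean_months[d$stage == "preclinical_to_symptomatic"], c(50, 50))
  # zero exit probability is an infinite sojourn, not an error
  z <- null_params()
  expect_true(all(is.infinite(dwell_time_summary(z)$mean_months)))
})

test_that("shipped variants hit their dwell targets and are strictly ordered", {
  targets <- c(short_dwell = 10, medium_dwell = 15, long_dwell = 20)
  totals <- sapply(names(targets), function(v) total_dwell_years(test_variant(v)))
  for (v in names(targets)) {
    expect_true(all(abs(totals[, v] - targets[[v]]) / targets[[v]] <= 0.05), info = v)
  }
  expect_true(all(diff(totals["hpv16_18", ]) > 0))
  expect_true(all(diff(totals["other_hr", ]) > 0))
  # only the short-dwell (occult-lesion) variant has cytology-occult lesions
  expect_gt(test_variant("short_dwell")$occult_fraction, 0)
  expect_equal(test_variant("medium_dwell")$occult_fraction, 0)
})

test_that("calibration lands the no-screening lifetime risk in the plausible band", {
  for (v in c("short_dwell", "long_dwell")) {
    p <- test_variant(v)
    sol <- cohort_solve(empty_schedule(1975), p, test_demography(), unvaccinated())
    risk <- lifetime_risk(sol)
    expect_gt(risk, 0.5)
    expect_lt(risk, 2)
    expect_equal(risk, p$metadata$target_lifetime_risk, tolerance = 1e-3)
  }
})

test_that("empirical preclinical sojourn matches the analytic mean", {
  p <- test_variant("short_dwell")
  n <- 1e5
  sim <- simulate_cohort(empty_schedule(1975), p, zero_demography(),
                         unvaccinated(), n = n, seed = 11,
                         init = list(state = "PRECLINICAL_CANCER", month = 0))
  sojourn <- sim$women$diag_month + 1 # presented during cycle diag_month
  expect_true(all(sim$women$diag_mode == "SYMPTOMATIC"))
  mu <- 1 / p$symptomatic_detection_rate
  sd_geom <- sqrt(1 - p$symptomatic_detection_rate) / p$symptomatic_detection_rate
  expect_lt(abs(mean(sojourn) - mu), 3 * sd_geom / sqrt(n))
})

test_that("parameter validation rejects non-stochastic and out-of-range inputs", {
  p <- test_variant("medium_dwell")
  bad <- p; bad$hpv_sens <- 1.2
  expect_error(validate_params(bad), "out of \\[0, 1\\]")
  bad <- p; bad$progression_to_cancer <- 0.999
  expect_error(validate_params(bad), "exceed 1")
  bad <- p; bad$hpv_incidence$age <- c(1:84, 99)
  expect_error(validate_params(bad), "ages 0-84")
})

test_that("parameter files regenerate byte-for-byte and round-trip", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- generate_parameter_files(dir1, variants = "short_dwell", seed = 3L)
  p2 <- generate_parameter_files(dir2, variants = "short_dwell", seed = 3L)
  expect_identical(readLines(p1[["short_dwell"]]), readLines(p2[["short_dwell"]]))
  expect_identical(readLines(p1[["demography"]]), readLines(p2[["demography"]]))
  back <- read_params(p1[["short_dwell"]])
  ref <- make_variant("short_dwell", seed = 3L)
  expect_equal(back[setdiff(names(back), "metadata")],
               ref[setdiff(names(ref), "metadata")])
  # shipped fixtures load and validate
  shipped <- read_params(shipped_params_path("long_dwell"))
  expect_no_error(validate_params(shipped))
  expect_equal(shipped$variant_name, "long_dwell")
})

test_that("tidy and glance expose the variant in broom shape", {
  p <- test_variant("short_dwell")
  td <- tidy(p)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$transition),
                  c("clearance", "progression_to_precancer",
                    "regression_from_precancer", "progression_to_cancer"))
  g <- glance(p)
  expect_equal(nrow(g), 1)
  expect_equal(g$colposcopy_compliance, 0.79)
  expect_equal(g$treatment_compliance, 0.73)
})
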