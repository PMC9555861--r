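test_that("last-screen ages match the published worked examples", {
  # 1975 cohort, 10-yearly cytology: delay pushes the final screen from 65
  # down to 56 / 57 / 60 because shifted screens past 65 are dropped
  last_age <- function(by, freq, mod, delay) {
    last_routine_screen_age(build_schedule(scenario_spec(by, freq, mod, delay)))
  }
  expect_equal(last_age(1975, 10, "CYTOLOGY", 0), 65)
  expect_equal(last_age(1975, 10, "CYTOLOGY", 1), 56)
  expect_equal(last_age(1975, 10, "CYTOLOGY", 2), 57)
  expect_equal(last_age(1975, 10, "CYTOLOGY", 5), 60)
  # 1965 cohort, 5-yearly: a 1-year delay moves the final screen from 65 to 61
  expect_equal(last_age(1965, 5, "CYTOLOGY", 0), 65)
  expect_equal(last_age(1965, 5, "CYTOLOGY", 1), 61)
})

test_that("the 1985 10-yearly HPV screener switches modality at 35, not 30", {
  sch <- build_schedule(scenario_spec(1985, 10, "HPV_PRIMARY", 0))
  pre <- sch[sch$calendar_year < 2020, ]
  expect_equal(nrow(pre), 1L)
  expect_equal(pre$age_years, 25)
  expect_equal(pre$modality, "CYTOLOGY") # not yet switched at her last pre-disruption screen
  first_hpv <- sch[sch$modality == "HPV_PRIMARY", ][1, ]
  expect_equal(first_hpv$age_years, 35)
  expect_equal(first_hpv$calendar_year, 2020)
})

test_that("annual screeners re-reach age 65 under every delay", {
  for (by in c(1965, 1975, 1985)) {
    ages <- vapply(c(0, 1, 2, 5), function(d) {
      last_routine_screen_age(build_schedule(scenario_spec(by, 1, "CYTOLOGY", d)))
    }, numeric(1))
    expect_true(all(ages == 65))
  }
  # and outside the window the delayed schedule matches the undisturbed one
  s0 <- build_schedule(scenario_spec(1975, 1, "CYTOLOGY", 0))
  s2 <- build_schedule(scenario_spec(1975, 1, "CYTOLOGY", 2))
  expect_identical(s0$age_years[s0$calendar_year < 2020],
                   s2$age_years[s2$calendar_year < 2020])
  expect_setequal(setdiff(s0$calendar_year, s2$calendar_year), c(2020, 2021))
})

test_that("every grid cell's schedule satisfies the schedule invariants", {
  grid <- build_grid(grid_config())
  expect_equal(nrow(grid), 96 + 3)
  expect_equal(sum(grid$screening), 96)
  pol <- policy_rules()
  for (i in which(grid$screening)) {
    cell <- grid[i, ]
    sch <- schedule_for_cell(cell, pol)
    # no event inside the half-open delay window
    expect_false(any(sch$calendar_year >= 2020 &
                       sch$calendar_year < 2020 + cell$delay_years),
                 info = cell$cell_id)
    # age window respected, strictly increasing in time
    expect_true(all(sch$age_years >= pol$start_age & sch$age_years <= pol$stop_age))
    expect_false(is.unsorted(sch$month, strictly = TRUE))
    # inter-event gaps equal the frequency except across the window
    gaps <- diff(sch$calendar_year)
    across <- sch$calendar_year[-nrow(sch)] < 2020 & sch$calendar_year[-1] >= 2020
    expect_true(all(gaps[!across] == cell$frequency_years), info = cell$cell_id)
  }
})

test_that("delays never add screens and nest outside the undisturbed window", {
  grid <- build_grid(grid_config())
  cells <- grid[grid$screening, ]
  for (key in split(cells, ~ birth_year + frequency_years + modality)) {
    key <- key[order(key$delay_years), ]
    schedules <- lapply(seq_len(nrow(key)), function(i) build_schedule(key[i, ]))
    n_screens <- vapply(schedules, nrow, integer(1))
    expect_false(is.unsorted(rev(n_screens))) # non-increasing in delay
    dates0 <- schedules[[1]]$calendar_year
    for (j in seq_along(schedules)[-1]) {
      d <- key$delay_years[j]
      inside <- dates0[dates0 >= 2020 & dates0 < 2020 + d]
      expect_false(any(schedules[[j]]$calendar_year %in% inside))
    }
  }
})

test_that("grid configuration is extensible and validates its enumerations", {
  small <- build_grid(grid_config(cohorts = 1975L, frequencies = 3L))
  expect_equal(sum(small$screening), 1 * 1 * 2 * 4)
  expect_error(grid_config(modalities = "SELF_SAMPLING"), "unknown modality")
  expect_error(grid_config(delays = -1L), "invalid")
})

test_that("degenerate schedules behave as defined", {
  expect_true(is.na(last_routine_screen_age(empty_schedule(1975))))
  # a frequency longer than the eligible age span leaves a single screen
  one <- build_schedule(scenario_spec(1999, 45, "CYTOLOGY", 0))
  expect_equal(one$age_years, 21)
  expect_equal(last_routine_screen_age(one), 21)
  # a delay may legally push every remaining screen past the stop age
  late <- build_schedule(scenario_spec(1957, 5, "CYTOLOGY", 5),
                         policy = policy_rules())
  expect_true(all(late$calendar_year < 2020))
})
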