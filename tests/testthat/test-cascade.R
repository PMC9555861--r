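test_that("perfect specificity means lesion-free women always screen negative", {
  p <- test_variant("medium_dwell")
  p$cyto_spec <- 1; p$hpv_spec <- 1
  women <- health_states(rep("HEALTHY", 200))
  set.seed(1)
  out <- perform_screen(women, "CYTOLOGY", p)
  expect_true(all(out$result == "NEGATIVE"))
  expect_false(any(out$referred_to_colposcopy))
  out <- perform_screen(women, "HPV_PRIMARY", p)
  expect_true(all(out$result == "NEGATIVE"))
})

test_that("cytology never detects occult lesions, at any sensitivity", {
  p <- test_variant("short_dwell")
  p$cyto_sens_precancer <- 1; p$cyto_sens_cancer <- 1
  women <- health_states(rep(c("PRECANCER", "PRECLINICAL_CANCER"), 100),
                         "HPV16_18", occult = TRUE)
  set.seed(2)
  out <- perform_screen(women, "CYTOLOGY", p)
  expect_true(all(out$result == "NEGATIVE"))
})

test_that("HPV16/18 positives are referred directly, other-HR via triage", {
  p <- test_variant("medium_dwell")
  p$hpv_sens <- 1
  set.seed(3)
  w16 <- perform_screen(health_states(rep("HPV_INFECTED", 50), "HPV16_18"),
                        "HPV_PRIMARY", p)
  expect_true(all(w16$result == "POSITIVE"))
  expect_true(all(w16$genotype_call == "HPV16_18"))
  expect_true(all(w16$referred_to_colposcopy))
  expect_true(all(is.na(w16$triage_cytology_result)))
  woth <- perform_screen(health_states(rep("HPV_INFECTED", 2000), "OTHER_HR"),
                         "HPV_PRIMARY", p)
  expect_true(all(woth$genotype_call == "OTHER_HR"))
  expect_true(all(woth$triage_cytology_result %in% c("NEGATIVE", "ASCUS_PLUS")))
  expect_equal(woth$referred_to_colposcopy,
               woth$triage_cytology_result == "ASCUS_PLUS")
  # triage on an infected (lesion-free) woman is a false-positive cytology
  expect_true(within_3se(mean(woth$referred_to_colposcopy), 1 - p$cyto_spec, 2000))
})

test_that("screen-outcome invariants hold across random screens", {
  p <- test_variant("short_dwell")
  set.seed(4)
  labels <- sample(c("HEALTHY", "HPV_INFECTED", "PRECANCER", "PRECLINICAL_CANCER"),
                   4000, replace = TRUE)
  women <- health_states(
    labels,
    genotype = ifelse(labels == "HEALTHY", "NONE",
                      sample(c("HPV16_18", "OTHER_HR"), 4000, replace = TRUE)),
    occult = labels %in% c("PRECANCER", "PRECLINICAL_CANCER") &
      stats::runif(4000) < 0.3
  )
  for (mod in c("CYTOLOGY", "HPV_PRIMARY")) {
    out <- perform_screen(women, mod, p)
    expect_true(all(out$result[out$referred_to_colposcopy] == "POSITIVE"))
    if (mod == "CYTOLOGY") expect_true(all(out$genotype_call == "NONE"))
    else expect_true(all((out$genotype_call != "NONE") == (out$result == "POSITIVE")))
  }
  expect_error(perform_screen(health_states("DEAD_OTHER"), "CYTOLOGY", p),
               "ineligible")
})

test_that("management recovers the stated compliance inputs over 1e5 referrals", {
  p <- test_variant("medium_dwell")
  n <- 1e5
  referred <- perform_screen(health_states(rep("PRECANCER", n), "HPV16_18"),
                             "HPV_PRIMARY", `[[<-`(p, "hpv_sens", 1))
  referred <- referred[referred$referred_to_colposcopy, ]
  set.seed(5)
  res <- manage_positive(referred, p)
  expect_true(within_3se(mean(res$attended_colposcopy), 0.79, nrow(res)))
  detected <- res[res$lesion_detected, ]
  expect_true(within_3se(mean(detected$treated), 0.73, nrow(detected)))
  # treated => detected => attended, and untreated detections enter surveillance
  expect_true(all(res$attended_colposcopy[res$lesion_detected]))
  expect_true(all(res$lesion_detected[res$treated]))
  expect_true(all(res$new_label[res$treated] == "HEALTHY"))
  expect_true(all(res$new_genotype[res$treated] == "NONE"))
  expect_equal(is.na(res$surveillance_in_months),
               !(res$lesion_detected & !res$treated))
})

test_that("management edge cases follow the forced pathways", {
  p <- test_variant("medium_dwell")
  ref <- function(states) {
    out <- perform_screen(states, "HPV_PRIMARY", `[[<-`(p, "hpv_sens", 1))
    out[out$referred_to_colposcopy, ]
  }
  set.seed(6)
  # zero colposcopy compliance: nobody attends, states unchanged
  p0 <- p; p0$colposcopy_compliance <- 0
  res <- manage_positive(ref(health_states(rep("PRECANCER", 50), "HPV16_18")), p0)
  expect_false(any(res$attended_colposcopy))
  expect_true(all(res$new_label == "PRECANCER"))
  # perfect colposcopy on preclinical cancer: all screen-detected
  p1 <- p; p1$colposcopy_compliance <- 1; p1$colposcopy_sens <- 1
  res <- manage_positive(ref(health_states(rep("PRECLINICAL_CANCER", 50), "HPV16_18")), p1)
  expect_true(all(res$cancer_screen_detected))
  expect_true(all(res$new_label == "DIAGNOSED_CANCER"))
  # calling management on non-referred outcomes is a contract violation
  neg <- perform_screen(health_states(rep("HEALTHY", 5)), "CYTOLOGY",
                        `[[<-`(p, "cyto_spec", 1))
  expect_error(manage_positive(neg, p), "non-referred")
})

test_that("false-positive referrals match the specificity accounting", {
  p <- test_variant("medium_dwell")
  n <- 1e5
  set.seed(7)
  out <- perform_screen(health_states(rep("HEALTHY", n)), "CYTOLOGY", p)
  expected <- (1 - p$cyto_spec) * (1 - p$hpv_spec)
  expect_true(within_3se(mean(out$referred_to_colposcopy), expected, n))
})
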