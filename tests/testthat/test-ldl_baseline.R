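test_that("each qualification rule excludes what it should", {
  labs <- dplyr::bind_rows(
    mk_lab("p1", -400, "ldl", 110),             # qualifies
    mk_lab("p1", -200, "ldl", 100),             # too recent (<= 1 year)
    mk_lab("p1", -500, "ldl", 120, inpatient = TRUE),  # in hospital
    mk_lab("p1", -600, "ldl", 130),             # killed by nearby low albumin
    mk_lab("p1", -590, "albumin", 2.8),         # 10 days after the -600 LDL
    mk_lab("p1", -366, "ldl", 105)              # boundary: exactly 366 days out
  )
  b <- toy_bundle(labs = labs)
  q <- qualifying_ldl(b, "p1", D0)
  expect_setequal(q$value, c(110, 105))

  # strictly-more-than-365-days boundary
  b365 <- toy_bundle(labs = mk_lab("p1", -365, "ldl", 100))
  expect_equal(nrow(qualifying_ldl(b365, "p1", D0)), 0)

  # albumin window is bidirectional and inclusive at 30 days
  b_alb <- toy_bundle(labs = dplyr::bind_rows(
    mk_lab("p1", -600, "ldl", 130),
    mk_lab("p1", -630, "albumin", 2.9),   # 30 days before: excludes
    mk_lab("p1", -800, "ldl", 125),
    mk_lab("p1", -831, "albumin", 2.9)    # 31 days before: does not
  ))
  expect_equal(qualifying_ldl(b_alb, "p1", D0)$value, 125)
  # albumin at exactly 3.0 g/dL is not "less than 3"
  b_alb3 <- toy_bundle(labs = dplyr::bind_rows(
    mk_lab("p1", -600, "ldl", 130), mk_lab("p1", -605, "albumin", 3.0)
  ))
  expect_equal(qualifying_ldl(b_alb3, "p1", D0)$value, 130)

  # measurements before age 18 are excluded
  b_young <- toy_bundle(
    patients = mk_patients("p1", birth = D0 - round(20 * 365.25)),
    labs = dplyr::bind_rows(mk_lab("p1", -800, "ldl", 90),   # age ~17.8
                            mk_lab("p1", -380, "ldl", 95))   # age ~18.9
  )
  expect_equal(qualifying_ldl(b_young, "p1", D0)$value, 95)
})

test_that("measurements on/after the first statin mention are excluded", {
  labs <- dplyr::bind_rows(
    mk_lab("p1", -900, "ldl", 140),   # before statin: qualifies
    mk_lab("p1", -700, "ldl", 100),   # same day as first statin: excluded
    mk_lab("p1", -500, "ldl", 90)     # after: excluded
  )
  b <- toy_bundle(labs = labs, meds = mk_med("p1", -700, "atorvastatin"))
  expect_equal(qualifying_ldl(b, "p1", D0)$value, 140)
})

test_that("baseline median follows the stated conventions", {
  expect_equal(baseline_median(c(88, 102, 130)), 102)
  expect_equal(baseline_median(c(100, 120)), 110)
  set.seed(1)
  v <- runif(7, 50, 200)
  expect_equal(baseline_median(sample(v)), baseline_median(v))
  expect_gte(baseline_median(v), min(v))
  expect_lte(baseline_median(v), max(v))
  expect_error(baseline_median(numeric(0)), class = "sepsisldl_no_baseline")
})

test_that("chronic-illness exclusions use a strict one-year lookback", {
  mk <- function(day) {
    toy_bundle(codes = mk_code("p1", day, "585.9"),
               labs = mk_lab("p1", -400, "ldl", 100))
  }
  ep_of <- function(b) toy_index_episode(b)
  # CKD code 100 days pre-index: excluded
  b <- mk(-100)
  expect_equal(nrow(apply_chronic_exclusions(ep_of(b), b)), 0)
  # only 3 years pre-index: retained
  b_old <- mk(-1095)
  expect_equal(nrow(apply_chronic_exclusions(ep_of(b_old), b_old)), 1)
  # code on day 0 is not lookback history
  b0 <- mk(0)
  expect_equal(nrow(apply_chronic_exclusions(ep_of(b0), b0)), 1)
  # no exclusion codes: retained
  b_none <- toy_bundle(labs = mk_lab("p1", -400, "ldl", 100))
  expect_equal(nrow(apply_chronic_exclusions(ep_of(b_none), b_none)), 1)
})

test_that("growing the exclusion list is monotone", {
  sim <- generate_ehr_bundle(sim_params(n_patients = 400, seed = 13))
  eps <- select_index_episodes(find_infection_episodes(sim$bundle))
  cfg <- default_code_config()
  cfg_small <- cfg
  cfg_small$exclusion_condition_codes <- list(ICD9CM = "042")
  kept_small <- apply_chronic_exclusions(eps, sim$bundle, cfg_small)
  kept_full <- apply_chronic_exclusions(eps, sim$bundle, cfg)
  # every episode dropped under the small list is also dropped under the full one
  expect_equal(nrow(dplyr::anti_join(kept_full, kept_small,
                                     by = c("patient_id", "admit_date"))), 0)
})

test_that("closest-to-admission value ignores qualification and breaks ties early", {
  b <- toy_bundle(labs = dplyr::bind_rows(mk_lab("p1", -400, "ldl", 140),
                                          mk_lab("p1", -20, "ldl", 95)))
  expect_equal(closest_to_admission_ldl(b, "p1", D0), 95)
  b1 <- toy_bundle(labs = mk_lab("p1", -300, "ldl", 111))
  expect_equal(closest_to_admission_ldl(b1, "p1", D0), 111)
  b2 <- toy_bundle(labs = dplyr::bind_rows(mk_lab("p1", -5, "ldl", 101),
                                           mk_lab("p1", 5, "ldl", 133)))
  expect_equal(closest_to_admission_ldl(b2, "p1", D0), 101)
  b3 <- toy_bundle(labs = mk_lab("p1", -40, "hdl", 50))
  expect_true(is.na(closest_to_admission_ldl(b3, "p1", D0)))
})

test_that("baseline profile reports medians and EHR length", {
  labs <- dplyr::bind_rows(
    mk_lab("p1", -400, "ldl", 100), mk_lab("p1", -600, "ldl", 120),
    mk_lab("p1", -500, "hdl", 40), mk_lab("p1", -450, "hdl", 60),
    mk_lab("p1", -500, "triglycerides", 150),
    mk_lab("p1", -500, "bmi", 28)
  )
  b <- toy_bundle(labs = labs)
  prof <- ldl_baselines(b, toy_index_episode(b))
  expect_equal(prof$ldl_baseline, 110)
  expect_equal(prof$n_qualifying, 2L)
  expect_equal(prof$hdl_median, 50)
  expect_equal(prof$tg_median, 150)
  expect_equal(prof$bmi_median, 28)
  # record span: day -600 to discharge at day +5
  expect_equal(prof$ehr_length_years, 605 / 365.25, tolerance = 1e-9)
})
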