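test_that("lab baselines are extrema over the 1-year-to-discharge span", {
  labs <- dplyr::bind_rows(
    mk_lab("p1", -200, "creatinine", 0.9),
    mk_lab("p1", 0, "creatinine", 1.8, inpatient = TRUE),
    mk_lab("p1", -30, "platelets", 250),
    mk_lab("p1", 1, "platelets", 95, inpatient = TRUE),
    mk_lab("p1", -400, "creatinine", 0.4)  # outside the span
  )
  b <- toy_bundle(labs = labs)
  bl <- compute_lab_baselines(b, toy_index_episode(b))
  expect_equal(bl$creatinine_baseline, 0.9)
  expect_equal(bl$platelet_baseline, 250)
  expect_true(is.na(bl$bilirubin_baseline))
})

test_that("renal criterion: doubling of baseline creatinine, inclusive", {
  expect_true(renal_failure(1.6, baseline = 0.8))
  expect_false(renal_failure(1.59, baseline = 0.8))
  expect_false(renal_failure(numeric(0), baseline = 0.8))
  expect_false(renal_failure(5, baseline = NA_real_))
  # ratio criterion: invariant to rescaling all values
  for (k in c(0.25, 3, 17)) {
    expect_equal(renal_failure(k * c(1.0, 1.7), baseline = k * 0.8),
                 renal_failure(c(1.0, 1.7), baseline = 0.8))
  }
})

test_that("hepatic criterion: absolute 2.0 mg/dL and doubling, jointly", {
  expect_true(hepatic_failure(2.4, baseline = 0.6))
  expect_false(hepatic_failure(1.9, baseline = 0.6))   # below absolute threshold
  expect_false(hepatic_failure(2.5, baseline = 1.5))   # not doubled
  expect_true(hepatic_failure(c(1.0, 3.0), baseline = 1.5))
  expect_false(hepatic_failure(2.4, baseline = NA_real_))
})

test_that("hematologic criterion: <100 with >=50% decline from a >=100 baseline", {
  expect_true(hematologic_failure(95, baseline = 210))
  expect_false(hematologic_failure(40, baseline = 90))   # baseline too low
  expect_false(hematologic_failure(99, baseline = 150))  # 34% decline only
  expect_true(hematologic_failure(50, baseline = 100))   # boundary: exactly 50%
  expect_false(hematologic_failure(numeric(0), baseline = 210))
})

test_that("cardiovascular criterion requires norepinephrine, or dopamine/dobutamine plus an administration code", {
  ep <- function(b) toy_index_episode(b)
  b1 <- toy_bundle(meds = mk_med("p1", 0, "norepinephrine"))
  expect_true(cardiovascular_failure(b1, ep(b1)))
  b2 <- toy_bundle(meds = mk_med("p1", 0, "dobutamine"))
  expect_false(cardiovascular_failure(b2, ep(b2)))
  b3 <- toy_bundle(meds = mk_med("p1", 1, "dopamine"),
                   codes = mk_code("p1", 1, "00.17", system = "PROC"))
  expect_true(cardiovascular_failure(b3, ep(b3)))
  # vasopressor outside the window does not count
  b4 <- toy_bundle(meds = mk_med("p1", 3, "norepinephrine"))
  expect_false(cardiovascular_failure(b4, ep(b4)))
})

test_that("respiratory criterion is the conjunction of ventilation and ICU", {
  ep <- function(b) toy_index_episode(b)
  b1 <- toy_bundle(codes = mk_code("p1", 0, "96.70", system = "PROC"), icu = TRUE)
  expect_true(respiratory_failure(b1, ep(b1)))
  b2 <- toy_bundle(codes = mk_code("p1", 0, "96.70", system = "PROC"))
  expect_false(respiratory_failure(b2, ep(b2)))
  b3 <- toy_bundle(icu = TRUE)
  expect_false(respiratory_failure(b3, ep(b3)))
  # ICU marker code in window substitutes for the admission flag
  b4 <- toy_bundle(codes = dplyr::bind_rows(
    mk_code("p1", 0, "96.70", system = "PROC"),
    mk_code("p1", 0, "ICU", system = "PROC")
  ))
  expect_true(respiratory_failure(b4, ep(b4)))
})

test_that("classification combines explicit codes and organ criteria", {
  # explicit code alone
  b1 <- toy_bundle(codes = mk_code("p1", 0, "R65.21", system = "ICD10"))
  c1 <- classify_sepsis(b1, toy_index_episode(b1))
  expect_true(c1$sepsis)
  expect_true(c1$explicit_code)
  expect_false(any(unlist(c1[c("cardiovascular", "respiratory", "renal",
                               "hepatic", "hematologic")])))
  # organ criterion alone
  b2 <- toy_bundle(labs = dplyr::bind_rows(
    mk_lab("p1", -100, "creatinine", 0.8),
    mk_lab("p1", 1, "creatinine", 1.7, inpatient = TRUE)
  ))
  c2 <- classify_sepsis(b2, toy_index_episode(b2))
  expect_true(c2$sepsis)
  expect_true(c2$renal)
  expect_false(c2$explicit_code)
  expect_match(c2$evidence[[1]], "renal")
  # no window evidence at all
  c3 <- classify_sepsis(toy_bundle(), toy_index_episode(toy_bundle()))
  expect_false(c3$sepsis)
  expect_length(c3$evidence[[1]], 0)
})

test_that("events outside days -1..+1 never set organ flags (window locality)", {
  b <- toy_bundle(
    codes = dplyr::bind_rows(mk_code("p1", 3, "R65.21", system = "ICD10"),
                             mk_code("p1", -2, "96.70", system = "PROC")),
    meds = mk_med("p1", 2, "norepinephrine"),
    labs = dplyr::bind_rows(mk_lab("p1", -100, "creatinine", 0.8),
                            mk_lab("p1", 4, "creatinine", 3.0, inpatient = TRUE)),
    icu = TRUE
  )
  call <- classify_sepsis(b, toy_index_episode(b))
  expect_false(call$sepsis)
})

test_that("adding qualifying window evidence never turns sepsis off (monotonicity)", {
  b <- toy_bundle(labs = dplyr::bind_rows(
    mk_lab("p1", -100, "creatinine", 0.8),
    mk_lab("p1", 1, "creatinine", 1.7, inpatient = TRUE)
  ))
  before <- classify_sepsis(b, toy_index_episode(b))
  expect_true(before$sepsis)
  b2 <- plant_sepsis_evidence(b, "p1", "cardiovascular")
  after <- classify_sepsis(b2, toy_index_episode(b2))
  expect_true(after$sepsis)
  expect_true(after$renal && after$cardiovascular)
})

test_that("ICU and death outcomes are copied from the index admission", {
  b <- toy_bundle(icu = TRUE, died = TRUE)
  call <- classify_sepsis(b, toy_index_episode(b))
  expect_true(call$icu_admission)
  expect_true(call$in_hospital_death)
})
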