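test_that("episodes need an infection code in-admission and an antibiotic on day -1..+1", {
  # antibiotic on day -1: qualifies
  b <- toy_bundle()
  eps <- find_infection_episodes(b)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$antibiotic_day, -1L)
  expect_equal(eps$infection_code, "486")

  # antibiotic only on day +2: outside the window
  b2 <- ehr_bundle(mk_patients("p1"), mk_admission("p1"),
                   mk_code("p1", 0, "486"), mk_med("p1", 2, "vancomycin"),
                   empty_of(mk_lab("p1", 0, "ldl", 1)))
  expect_equal(nrow(find_infection_episodes(b2)), 0)

  # infection code dated outside the admission span does not qualify
  b3 <- ehr_bundle(mk_patients("p1"), mk_admission("p1"),
                   mk_code("p1", -3, "486"), mk_med("p1", 0, "vancomycin"),
                   empty_of(mk_lab("p1", 0, "ldl", 1)))
  expect_equal(nrow(find_infection_episodes(b3)), 0)

  # a non-infection code does not qualify
  b4 <- ehr_bundle(mk_patients("p1"), mk_admission("p1"),
                   mk_code("p1", 0, "V70.0"), mk_med("p1", 0, "vancomycin"),
                   empty_of(mk_lab("p1", 0, "ldl", 1)))
  expect_equal(nrow(find_infection_episodes(b4)), 0)
})

test_that("patients under 18 at admission are excluded", {
  b <- toy_bundle(patients = mk_patients("p1", birth = D0 - round(17.5 * 365.25)))
  expect_equal(nrow(find_infection_episodes(b)), 0)
  b18 <- toy_bundle(patients = mk_patients("p1", birth = D0 - round(18.5 * 365.25)))
  expect_equal(nrow(find_infection_episodes(b18)), 1)
})

test_that("index selection takes the first episode, or the first after the anchor", {
  adm <- dplyr::bind_rows(mk_admission("p1", as.Date("2001-05-01")),
                          mk_admission("p1", as.Date("2004-02-02")))
  codes <- dplyr::bind_rows(mk_code("p1", 0, "486", ref = as.Date("2001-05-01")),
                            mk_code("p1", 0, "486", ref = as.Date("2004-02-02")))
  meds <- dplyr::bind_rows(mk_med("p1", 0, "vancomycin", ref = as.Date("2001-05-01")),
                           mk_med("p1", 0, "vancomycin", ref = as.Date("2004-02-02")))
  b <- ehr_bundle(mk_patients("p1", birth = as.Date("1940-01-01")), adm, codes,
                  meds, empty_of(mk_lab("p1", 0, "ldl", 1)))
  eps <- find_infection_episodes(b)
  expect_equal(nrow(eps), 2)
  idx <- select_index_episodes(eps)
  expect_equal(idx$admit_date, as.Date("2001-05-01"))
  # anchored: first episode strictly after the anchor date
  anchored <- select_index_episodes(
    eps, tibble::tibble(patient_id = "p1", anchor_date = as.Date("2002-03-03"))
  )
  expect_equal(anchored$admit_date, as.Date("2004-02-02"))
  # singleton is its own index
  one <- select_index_episodes(eps[2, ])
  expect_equal(one$admit_date, as.Date("2004-02-02"))
})

test_that("same-day tie breaks deterministically by code", {
  codes <- dplyr::bind_rows(mk_code("p1", 0, "599.0"), mk_code("p1", 0, "486"))
  b <- ehr_bundle(mk_patients("p1"), mk_admission("p1"), codes,
                  mk_med("p1", 0, "vancomycin"), empty_of(mk_lab("p1", 0, "ldl", 1)))
  idx <- select_index_episodes(find_infection_episodes(b))
  expect_equal(idx$infection_code, "486")
})

test_that("non-qualifying events never change the episode set (locality)", {
  b <- toy_bundle()
  eps <- find_infection_episodes(b)
  noisy <- toy_bundle(
    codes = dplyr::bind_rows(mk_code("p1", -50, "428.0"), mk_code("p1", 1, "V70.0")),
    meds = mk_med("p1", 0, "aspirin"),
    labs = mk_lab("p1", -500, "ldl", 120)
  )
  expect_equal(find_infection_episodes(noisy) |> dplyr::select(-dplyr::any_of("n")),
               eps)
})

test_that("shrinking the infection-code list never adds episodes (monotonicity)", {
  sim <- generate_ehr_bundle(sim_params(n_patients = 300, seed = 8))
  cfg <- default_code_config()
  full <- find_infection_episodes(sim$bundle, cfg)
  cfg_small <- cfg
  cfg_small$infection_codes <- list(ICD9CM = "486")
  small <- find_infection_episodes(sim$bundle, cfg_small)
  expect_lte(nrow(small), nrow(full))
  expect_equal(nrow(dplyr::anti_join(small, full, by = c("patient_id", "admit_date"))), 0)
})
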