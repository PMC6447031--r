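test_that("generation is deterministic for a fixed seed and empty at n = 0", {
  a <- generate_ehr_bundle(sim_params(n_patients = 150, seed = 5))
  b <- generate_ehr_bundle(sim_params(n_patients = 150, seed = 5))
  expect_identical(a$truth, b$truth)
  for (tab in c("patients", "admissions", "coded_events", "medication_events",
                "labs", "genotypes")) {
    expect_identical(a$bundle[[tab]], b$bundle[[tab]])
  }
  e <- generate_ehr_bundle(sim_params(n_patients = 0, seed = 5))
  expect_equal(nrow(e$bundle$patients), 0)
  expect_equal(nrow(e$bundle$labs), 0)
  expect_equal(nrow(e$truth), 0)
})

test_that("invalid parameters are rejected", {
  expect_error(sim_params(grs_target_r2 = 1), class = "sepsisldl_param_error")
  expect_error(sim_params(grs_target_r2 = 0), class = "sepsisldl_param_error")
  expect_error(sim_params(n_patients = -1), class = "sepsisldl_param_error")
  expect_error(sim_params(sepsis_base_rate = 1.2), class = "sepsisldl_param_error")
  expect_error(
    generate_ehr_bundle(sim_params(n_patients = 10, seed = 1,
                                   ldl_comorbidity_shift = -40)),
    class = "sepsisldl_param_error"
  )
})

test_that("comorbidity prevalences and LDL moments match their targets", {
  n <- 20000
  sim <- generate_ehr_bundle(sim_params(n_patients = n, seed = 99))
  prev <- default_comorbidity_prevalences()
  # category flag = a lookback diagnosis code; check one high- and one
  # low-prevalence category against 3 binomial SDs
  tab <- measured_analysis_table(sim$bundle, lipid_covariates = FALSE)
  for (cat in c("chronic_pulmonary_disease", "dementia")) {
    p <- prev[[cat]]
    obs <- mean(tab[[paste0("cm_", cat)]])
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / nrow(tab)) + 0.01)
  }
  # marginal LDL moments within 3 SEs at n = 20000
  ldl <- sim$truth$ldl_true
  expect_lt(abs(mean(ldl) - 103.4), 3 * 32.6 / sqrt(n))
  expect_lt(abs(sd(ldl) - 32.6), 3 * 32.6 / sqrt(2 * n))
})

test_that("GRS noise calibration follows the closed form and Monte-Carlo", {
  # single SNP, beta = 1, maf = 0.5: Var(G) = 0.5, so r2 = 0.5 needs sigma^2 = 0.5
  expect_equal(calibrate_grs_noise(tibble::tibble(beta = 1, maf = 0.5), 0.5),
               sqrt(0.5), tolerance = 1e-12)
  expect_error(calibrate_grs_noise(tibble::tibble(beta = 1, maf = 0.5), 1),
               class = "sepsisldl_param_error")
  expect_error(calibrate_grs_noise(tibble::tibble(beta = 1, maf = 0.5), 0),
               class = "sepsisldl_param_error")
  # Monte-Carlo at n = 50000: realized r2 within 0.01 of the target
  set.seed(42)
  w <- default_snp_weights()
  n <- 50000
  g <- matrix(rbinom(n * nrow(w), 2, rep(w$maf, each = n)), nrow = n)
  score <- as.numeric(g %*% w$beta)
  sig <- calibrate_grs_noise(w, 0.058)
  ldl <- score + rnorm(n, 0, sig)
  expect_lt(abs(cor(score, ldl)^2 - 0.058), 0.01)
})

test_that("confounding structure behaves as designed", {
  # with no direct effect but active confounding, the marginal LDL-sepsis
  # association is negative
  sim <- generate_ehr_bundle(sim_params(n_patients = 6000, seed = 21))
  z <- scale(sim$truth$ldl_true)[, 1]
  fit <- glm(sim$truth$sepsis ~ z, family = binomial())
  expect_lt(coef(fit)[["z"]], 0)
  expect_lt(summary(fit)$coefficients["z", "Pr(>|z|)"], 0.05)
  # with the burden channel switched off, LDL and sepsis are independent
  sim0 <- generate_ehr_bundle(sim_params(n_patients = 6000, seed = 22,
                                         ldl_comorbidity_shift = 0,
                                         comorbidity_logor = 0))
  z0 <- scale(sim0$truth$ldl_true)[, 1]
  fit0 <- glm(sim0$truth$sepsis ~ z0, family = binomial())
  ci <- coef(fit0)[["z0"]] + c(-1, 1) * 1.96 * summary(fit0)$coefficients["z0", "Std. Error"]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("planted evidence is minimal and criterion-specific", {
  for (crit in c("explicit_code", "cardiovascular", "respiratory",
                 "renal", "hepatic", "hematologic")) {
    b <- toy_bundle()
    b <- plant_sepsis_evidence(b, "p1", crit)
    call <- classify_sepsis(b, toy_index_episode(b))
    expect_true(call$sepsis, info = crit)
    expect_true(call[[crit]], info = crit)
    others <- setdiff(c("explicit_code", "cardiovascular", "respiratory",
                        "renal", "hepatic", "hematologic"), crit)
    expect_false(any(unlist(call[others])), info = crit)
    expect_gt(length(call$evidence[[1]]), 0)
  }
  expect_error(plant_sepsis_evidence(toy_bundle(), "p1", "astral"),
               class = "sepsisldl_param_error")
  expect_error(plant_sepsis_evidence(toy_bundle(), "nobody", "renal"),
               class = "sepsisldl_param_error")
})

test_that("multi-episode generation exercises the first-episode rule", {
  sim <- generate_ehr_bundle(sim_params(n_patients = 800, seed = 31,
                                        multi_episode_rate = 0.4))
  eps <- find_infection_episodes(sim$bundle)
  expect_gt(nrow(eps), 800)  # some patients have several episodes
  idx <- select_index_episodes(eps)
  expect_equal(nrow(idx), dplyr::n_distinct(eps$patient_id))
  first <- eps |> dplyr::summarise(first = min(admit_date), .by = patient_id)
  m <- dplyr::inner_join(idx, first, by = "patient_id")
  expect_true(all(m$admit_date == m$first))
})
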