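#' Simulation parameters for the synthetic EHR generator
#'
#' Bundles every knob of [generate_ehr_bundle()] with validated defaults.
#' The defaults encode the study conditions the pipeline is designed for:
#' baseline LDL with mean 103.4 and SD 32.6 mg/dL, a genetic score calibrated
#' to explain 5.8% of LDL variance, and a comorbidity-burden confounder that
#' both lowers LDL and raises the odds of sepsis, ICU admission and
#' in-hospital death, so that the crude (unadjusted) LDL-sepsis odds ratio is
#' depressed to roughly 0.86 per SD while the direct LDL effect is zero.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param comorbidity_prevalences Named vector of per-category prevalences
#'   (names must match the config's Charlson categories).
#' @param ldl_mean,ldl_sd Marginal mean and SD of true baseline LDL (mg/dL).
#' @param ldl_comorbidity_shift Shift in true LDL (mg/dL) per unit of
#'   comorbidity burden (negative: sicker patients have lower LDL).
#' @param direct_ldl_logor_per_sd Direct causal log-odds of sepsis per 1-SD
#'   increase of true LDL (0 under the no-direct-effect null).
#' @param comorbidity_logor Log-odds of sepsis per unit burden.
#' @param sepsis_base_rate,icu_base_rate,death_base_rate Approximate marginal
#'   outcome probabilities.
#' @param icu_comorbidity_logor,death_comorbidity_logor Burden effects on the
#'   secondary outcomes.
#' @param grs_target_r2 Fraction of true-LDL variance explained by the
#'   genetic score (default 0.058).
#' @param n_snps Number of SNPs used from the weight table.
#' @param snp_weights Optional tibble (`rsid`, `effect_allele`, `beta`,
#'   `maf`); default is the shipped synthetic 81-SNP table
#'   ([default_snp_weights()]).
#' @param ldl_assay_sd SD of per-measurement assay noise on recorded LDL
#'   values (mg/dL).
#' @param n_ldl_measurements Qualifying outpatient LDL draws per patient.
#' @param statin_rate,inpatient_ldl_rate,recent_ldl_rate,low_albumin_rate,
#'   extra_code_rate Background "noise" event rates that exercise the
#'   baseline-LDL exclusion rules and covariate lookback without altering
#'   outcome truth.
#' @param multi_episode_rate Fraction of patients given an additional
#'   infection admission (exercises the first-episode and prior-infection
#'   rules); off by default.
#' @param evidence_noise_rate Rate of random organ-dysfunction-like events
#'   (qualifying and non-qualifying, inside and outside the day -1..+1
#'   window).  Intended only for stress-testing the phenotyper; it breaks the
#'   alignment between generated outcome truth and the classifier, so it is 0
#'   by default.
#' @param admit_years Two-element integer vector: calendar range of index
#'   admissions.
#' @return A validated `sim_params` object (named list).
#' @export
sim_params <- function(n_patients = 4000,
                       seed = NULL,
                       comorbidity_prevalences = default_comorbidity_prevalences(),
                       ldl_mean = 103.4,
                       ldl_sd = 32.6,
                       ldl_comorbidity_shift = -8,
                       direct_ldl_logor_per_sd = 0,
                       comorbidity_logor = 0.5,
                       sepsis_base_rate = 0.15,
                       icu_base_rate = 0.08,
                       death_base_rate = 0.02,
                       icu_comorbidity_logor = 0.4,
                       death_comorbidity_logor = 0.5,
                       grs_target_r2 = 0.058,
                       n_snps = 81,
                       snp_weights = NULL,
                       ldl_assay_sd = 2,
                       n_ldl_measurements = 2,
                       statin_rate = 0.15,
                       inpatient_ldl_rate = 0.2,
                       recent_ldl_rate = 0.2,
                       low_albumin_rate = 0.05,
                       extra_code_rate = 0.5,
                       multi_episode_rate = 0,
                       evidence_noise_rate = 0,
                       admit_years = c(2010L, 2017L)) {
  if (is.null(snp_weights)) snp_weights <- default_snp_weights()
  snp_weights <- as_tibble(snp_weights)
  stopifnot(all(c("rsid", "beta", "maf") %in% names(snp_weights)))
  n_snps <- min(n_snps, nrow(snp_weights))
  snp_weights <- snp_weights[seq_len(n_snps), ]
  p <- list(
    n_patients = as.integer(n_patients), seed = seed,
    comorbidity_prevalences = comorbidity_prevalences,
    ldl_mean = ldl_mean, ldl_sd = ldl_sd,
    ldl_comorbidity_shift = ldl_comorbidity_shift,
    direct_ldl_logor_per_sd = direct_ldl_logor_per_sd,
    comorbidity_logor = comorbidity_logor,
    sepsis_base_rate = sepsis_base_rate, icu_base_rate = icu_base_rate,
    death_base_rate = death_base_rate,
    icu_comorbidity_logor = icu_comorbidity_logor,
    death_comorbidity_logor = death_comorbidity_logor,
    grs_target_r2 = grs_target_r2, n_snps = n_snps, snp_weights = snp_weights,
    ldl_assay_sd = ldl_assay_sd, n_ldl_measurements = as.integer(n_ldl_measurements),
    statin_rate = statin_rate, inpatient_ldl_rate = inpatient_ldl_rate,
    recent_ldl_rate = recent_ldl_rate, low_albumin_rate = low_albumin_rate,
    extra_code_rate = extra_code_rate, multi_episode_rate = multi_episode_rate,
    evidence_noise_rate = evidence_noise_rate,
    admit_years = as.integer(admit_years)
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  if (is.na(p$n_patients) || p$n_patients < 0) {
    abort("n_patients must be a non-negative integer", class = "sepsisldl_param_error")
  }
  if (!(p$grs_target_r2 > 0 && p$grs_target_r2 < 1)) {
    abort("grs_target_r2 must lie strictly in (0, 1)", class = "sepsisldl_param_error")
  }
  if (p$ldl_sd <= 0) abort("ldl_sd must be positive", class = "sepsisldl_param_error")
  probs <- c(p$comorbidity_prevalences, p$sepsis_base_rate, p$icu_base_rate,
             p$death_base_rate, p$statin_rate, p$inpatient_ldl_rate,
             p$recent_ldl_rate, p$low_albumin_rate, p$extra_code_rate,
             p$multi_episode_rate, p$evidence_noise_rate)
  if (any(probs < 0 | probs >= 1)) {
    abort("all probabilities/rates must lie in [0, 1)", class = "sepsisldl_param_error")
  }
  if (any(p$comorbidity_prevalences <= 0)) {
    abort("comorbidity prevalences must be positive", class = "sepsisldl_param_error")
  }
  invisible(p)
}

#' @rdname sim_params
#' @export
default_comorbidity_prevalences <- function() {
  c(myocardial_infarction = 0.13, congestive_heart_failure = 0.22,
    peripheral_vascular_disease = 0.09, cerebrovascular_disease = 0.18,
    dementia = 0.05, chronic_pulmonary_disease = 0.26, rheumatic_disease = 0.06,
    peptic_ulcer_disease = 0.03, mild_liver_disease = 0.08, diabetes = 0.25,
    diabetes_complications = 0.10, hemiplegia_paraplegia = 0.02,
    renal_disease = 0.08, malignancy = 0.18, severe_liver_disease = 0.07,
    metastatic_solid_tumor = 0.10, aids_hiv = 0.013)
}

#' Shipped synthetic SNP-weight table
#'
#' An 81-row synthetic weight table (`rsid`, `effect_allele`, `beta` in mg/dL
#' per effect allele, `maf`).  The rows are synthetic stand-ins for a
#' published genome-wide-significant LDL SNP panel (which is not
#' redistributable here); the betas are scaled so that the Hardy-Weinberg
#' score variance equals 5.8% of a 32.6^2 LDL variance.
#'
#' @return A tibble with columns `rsid`, `effect_allele`, `beta`, `maf`.
#' @export
default_snp_weights <- function() {
  read_snp_weights(system.file("extdata", "ldl_grs_weights_synthetic.csv",
                               package = "sepsisldl"))
}

#' Calibrate the non-genetic LDL noise for a target variance explained
#'
#' Under Hardy-Weinberg equilibrium the variance of the weighted-allele score
#' is `Var(G) = sum(beta^2 * 2 * maf * (1 - maf))`.  Returns the residual SD
#' `sigma` such that `Var(G) / (Var(G) + sigma^2)` equals `target_r2`.
#'
#' @param weights Tibble with `beta` and `maf` columns.
#' @param target_r2 Desired fraction of variance explained, strictly in (0, 1).
#' @return The residual SD (scalar).
#' @examples
#' calibrate_grs_noise(tibble::tibble(beta = 1, maf = 0.5), 0.5)  # 0.7071
#' @export
calibrate_grs_noise <- function(weights, target_r2) {
  if (!(is.numeric(target_r2) && length(target_r2) == 1 &&
        target_r2 > 0 && target_r2 < 1)) {
    abort("target_r2 must lie strictly in (0, 1)", class = "sepsisldl_param_error")
  }
  var_g <- grs_variance(weights)
  sqrt(var_g * (1 - target_r2) / target_r2)
}

grs_variance <- function(weights) {
  stopifnot(all(c("beta", "maf") %in% names(weights)))
  sum(weights$beta^2 * 2 * weights$maf * (1 - weights$maf))
}

sepsis_criteria <- c("explicit_code", "cardiovascular", "respiratory",
                     "renal", "hepatic", "hematologic")

#' Generate a synthetic EHR bundle with known ground truth
#'
#' Simulates a cohort of adult patients admitted to hospital with infection,
#' with the statistical structure the association analysis assumes:
#'
#' * a latent comorbidity burden (count of active Charlson categories) that
#'   lowers true baseline LDL (`ldl_comorbidity_shift` mg/dL per category)
#'   and raises the odds of sepsis, ICU admission and death;
#' * true LDL composed of a centred weighted-allele genetic score (scaled to
#'   explain `grs_target_r2` of the LDL variance), the burden shift, and
#'   Gaussian residual noise, with marginal mean `ldl_mean` and SD `ldl_sd`;
#' * sepsis realized from `logit(p) = alpha + comorbidity_logor * burden +
#'   direct_ldl_logor_per_sd * z(LDL)`, with minimal organ-dysfunction (or
#'   explicit-code) evidence planted for each case, the pathway chosen
#'   uniformly among the six; non-cases receive sub-threshold background labs
#'   only, so the rule-based phenotyper reproduces the simulated outcome
#'   exactly under default noise settings;
#' * event streams (diagnosis codes in the 1-year lookback, antibiotics on
#'   days -1..+1, statins, outpatient lipid panels, in-window organ labs)
#'   sufficient to drive every filter in the pipeline.
#'
#' @param params A [sim_params()] object.
#' @param config A [code_config][read_code_config].
#' @return A list of class `ehr_sim` with elements `bundle` (an
#'   [ehr_bundle()]) and `truth` (a tibble of per-patient latent values:
#'   burden, true LDL, raw genetic score, outcome probabilities and realized
#'   outcomes).  `truth` exists for parameter-recovery tests only and is
#'   never consumed by the pipeline.
#' @export
generate_ehr_bundle <- function(params = sim_params(), config = default_code_config()) {
  validate_sim_params(params)
  if (!is.null(params$seed)) set.seed(as.integer(params$seed))
  n <- params$n_patients
  if (n == 0) return(empty_ehr_sim(params, config))

  prev <- params$comorbidity_prevalences
  k <- length(prev)
  pid <- sprintf("P%06d", seq_len(n))

  # --- index admission -------------------------------------------------------
  yr0 <- as.Date(sprintf("%d-01-01", params$admit_years[1]))
  yr1 <- as.Date(sprintf("%d-12-31", params$admit_years[2]))
  admit <- yr0 + sample.int(as.integer(yr1 - yr0) + 1L, n, replace = TRUE) - 1L
  los <- sample(3:10, n, replace = TRUE)
  discharge <- admit + los

  sex <- sample(c("female", "male"), n, replace = TRUE)
  age <- runif(n, 25, 90)
  birth <- admit - round(age * 365.25)

  # --- latent structure ------------------------------------------------------
  cm <- matrix(rbinom(n * k, 1L, rep(prev, each = n)), nrow = n, ncol = k,
               dimnames = list(NULL, names(prev)))
  burden <- rowSums(cm)
  e_burden <- sum(prev)
  var_burden <- sum(prev * (1 - prev))

  w <- params$snp_weights
  m <- nrow(w)
  geno <- matrix(rbinom(n * m, 2L, rep(w$maf, each = n)), nrow = n, ncol = m,
                 dimnames = list(NULL, w$rsid))
  grs_raw <- as.numeric(geno %*% w$beta)
  var_g <- grs_variance(w)
  scale_g <- sqrt(params$grs_target_r2 * params$ldl_sd^2 / var_g)
  grs_centered <- grs_raw - sum(w$beta * 2 * w$maf)

  resid_var <- (1 - params$grs_target_r2) * params$ldl_sd^2 -
    params$ldl_comorbidity_shift^2 * var_burden
  if (resid_var <= 0) {
    abort(paste0("ldl_comorbidity_shift and comorbidity prevalences imply more ",
                 "non-genetic LDL variance than (1 - grs_target_r2) * ldl_sd^2"),
          class = "sepsisldl_param_error")
  }
  ldl_true <- params$ldl_mean + scale_g * grs_centered +
    params$ldl_comorbidity_shift * (burden - e_burden) +
    rnorm(n, 0, sqrt(resid_var))
  ldl_true <- pmax(ldl_true, 10)
  z <- (ldl_true - params$ldl_mean) / params$ldl_sd

  # --- outcomes --------------------------------------------------------------
  lp_sep <- qlogis(params$sepsis_base_rate) - params$comorbidity_logor * e_burden +
    params$comorbidity_logor * burden + params$direct_ldl_logor_per_sd * z
  p_sep <- plogis(lp_sep)
  sepsis <- rbinom(n, 1L, p_sep) == 1L
  criterion <- rep(NA_character_, n)
  criterion[sepsis] <- sample(sepsis_criteria, sum(sepsis), replace = TRUE)

  p_icu <- plogis(qlogis(params$icu_base_rate) - params$icu_comorbidity_logor * e_burden +
                    params$icu_comorbidity_logor * burden +
                    params$direct_ldl_logor_per_sd * z)
  icu <- rbinom(n, 1L, p_icu) == 1L
  icu <- icu | (sepsis & criterion == "respiratory" & !is.na(criterion))

  p_death <- plogis(qlogis(params$death_base_rate) -
                      params$death_comorbidity_logor * e_burden +
                      params$death_comorbidity_logor * burden +
                      params$direct_ldl_logor_per_sd * z)
  death <- rbinom(n, 1L, p_death) == 1L

  patients <- tibble(patient_id = pid, sex = sex, birth_date = birth)
  admissions <- tibble(patient_id = pid, admit_date = admit,
                       discharge_date = discharge, icu_flag = icu,
                       died_in_hospital = death)

  # --- coded events ----------------------------------------------------------
  infect <- config_codes(config, "infection_codes")
  inf_idx <- sample.int(nrow(infect), n, replace = TRUE)
  coded <- list(
    tibble(patient_id = pid, date = admit, system = infect$system[inf_idx],
           code = infect$code[inf_idx])
  )
  cat_codes <- config_category_codes(config)
  for (cat in names(prev)) {
    act <- which(cm[, cat] == 1L)
    if (length(act) == 0) next
    row <- cat_codes[cat_codes$category == cat, ]
    coded[[length(coded) + 1L]] <- tibble(
      patient_id = pid[act],
      date = admit[act] - sample(1:365, length(act), replace = TRUE),
      system = row$system, code = row$code
    )
  }
  old <- which(runif(n) < params$extra_code_rate)
  if (length(old) > 0) {
    row <- cat_codes[sample.int(nrow(cat_codes), length(old), replace = TRUE), ]
    coded[[length(coded) + 1L]] <- tibble(
      patient_id = pid[old],
      date = admit[old] - sample(400:900, length(old), replace = TRUE),
      system = row$system, code = row$code
    )
  }

  # --- medications -----------------------------------------------------------
  abx <- config$antibiotic_names
  meds <- list(
    tibble(patient_id = pid,
           date = admit + sample(-1:1, n, replace = TRUE),
           drug = sample(abx, n, replace = TRUE))
  )
  statin_users <- which(runif(n) < params$statin_rate)
  statin_start <- rep(as.Date(NA), n)
  if (length(statin_users) > 0) {
    start <- admit[statin_users] - sample(50:1200, length(statin_users), replace = TRUE)
    statin_start[statin_users] <- start
    drug <- sample(config$statin_names, length(statin_users), replace = TRUE)
    meds[[length(meds) + 1L]] <- tibble(
      patient_id = rep(pid[statin_users], 2L),
      date = c(start, start + 90L),
      drug = rep(drug, 2L)
    )
  }

  # --- labs ------------------------------------------------------------------
  labs <- list()
  n_ldl <- params$n_ldl_measurements
  if (n_ldl > 0) {
    labs[[length(labs) + 1L]] <- tibble(
      patient_id = rep(pid, each = n_ldl),
      date = rep(admit, each = n_ldl) -
        sample(400:1500, n * n_ldl, replace = TRUE),
      analyte = "ldl",
      value = pmax(rep(ldl_true, each = n_ldl) + rnorm(n * n_ldl, 0, params$ldl_assay_sd), 5),
      inpatient = FALSE
    )
  }
  if (length(statin_users) > 0) {  # post-statin (non-qualifying) LDL
    labs[[length(labs) + 1L]] <- tibble(
      patient_id = pid[statin_users], date = statin_start[statin_users] + 30L,
      analyte = "ldl", value = pmax(ldl_true[statin_users] * 0.7, 5),
      inpatient = FALSE
    )
  }
  recent <- which(runif(n) < params$recent_ldl_rate)
  if (length(recent) > 0) {
    labs[[length(labs) + 1L]] <- tibble(
      patient_id = pid[recent],
      date = admit[recent] - sample(30:300, length(recent), replace = TRUE),
      analyte = "ldl", value = pmax(ldl_true[recent] + rnorm(length(recent), 0, params$ldl_assay_sd), 5),
      inpatient = FALSE
    )
  }
  inpat <- which(runif(n) < params$inpatient_ldl_rate)
  if (length(inpat) > 0) {
    labs[[length(labs) + 1L]] <- tibble(
      patient_id = pid[inpat], date = admit[inpat], analyte = "ldl",
      value = pmax(ldl_true[inpat] * 0.8, 5), inpatient = TRUE
    )
  }
  lowalb <- which(runif(n) < params$low_albumin_rate)
  if (length(lowalb) > 0 && n_ldl > 0) {
    # near the patient's first qualifying LDL draw, knocking that draw out
    first_ldl <- labs[[1]] |> summarise(date = smin(.data$date), .by = "patient_id")
    tgt <- first_ldl$date[match(pid[lowalb], first_ldl$patient_id)]
    labs[[length(labs) + 1L]] <- tibble(
      patient_id = pid[lowalb],
      date = tgt + sample(-20:20, length(lowalb), replace = TRUE),
      analyte = "albumin", value = 2.5, inpatient = FALSE
    )
  }
  # covariate lipid panel / BMI, one each, well before admission
  cov_date <- admit - sample(400:1200, n, replace = TRUE)
  labs[[length(labs) + 1L]] <- tibble(
    patient_id = rep(pid, 3L),
    date = rep(cov_date, 3L),
    analyte = rep(c("hdl", "triglycerides", "bmi"), each = n),
    value = c(pmax(rnorm(n, 50.84, 17.1), 10),
              rgamma(n, shape = 2.22, scale = 72.5) + 20,
              pmax(rnorm(n, 30.3, 7.7), 14)),
    inpatient = FALSE
  )

  # --- organ-dysfunction labs and planted evidence ---------------------------
  pre_day <- admit - sample(30:300, n, replace = TRUE)
  win_day <- admit + sample(0:1, n, replace = TRUE)
  creat_pre <- exp(rnorm(n, log(0.9), 0.15))
  bili_pre <- runif(n, 0.3, 1.2)
  plt_pre <- runif(n, 150, 350)
  crit <- ifelse(is.na(criterion), "none", criterion)
  creat_win <- creat_pre * ifelse(crit == "renal", runif(n, 2.0, 2.6), runif(n, 0.75, 1.45))
  bili_win <- ifelse(crit == "hepatic", pmax(2.1, bili_pre * 2.2),
                     bili_pre * runif(n, 0.75, 1.45))
  plt_win <- ifelse(crit == "hematologic", pmin(95, plt_pre * 0.45),
                    plt_pre * runif(n, 0.6, 1.1))
  labs[[length(labs) + 1L]] <- tibble(
    patient_id = rep(pid, 6L),
    date = c(rep(pre_day, 3L), rep(win_day, 3L)),
    analyte = rep(rep(c("creatinine", "bilirubin_total", "platelets"), each = n), 2L),
    value = c(creat_pre, bili_pre, plt_pre, creat_win, bili_win, plt_win),
    inpatient = rep(c(FALSE, TRUE), each = 3L * n)
  )

  exp_cases <- which(crit == "explicit_code")
  if (length(exp_cases) > 0) {
    sev <- config_codes(config, "severe_sepsis_shock_codes")
    i <- sample.int(nrow(sev), length(exp_cases), replace = TRUE)
    coded[[length(coded) + 1L]] <- tibble(patient_id = pid[exp_cases],
                                          date = admit[exp_cases],
                                          system = sev$system[i], code = sev$code[i])
  }
  resp_cases <- which(crit == "respiratory")
  if (length(resp_cases) > 0) {
    vent <- config_codes(config, "ventilation_codes")
    i <- sample.int(nrow(vent), length(resp_cases), replace = TRUE)
    coded[[length(coded) + 1L]] <- tibble(patient_id = pid[resp_cases],
                                          date = admit[resp_cases],
                                          system = vent$system[i], code = vent$code[i])
    admissions$icu_flag[resp_cases] <- TRUE
  }
  cardio_cases <- which(crit == "cardiovascular")
  if (length(cardio_cases) > 0) {
    meds[[length(meds) + 1L]] <- tibble(patient_id = pid[cardio_cases],
                                        date = admit[cardio_cases],
                                        drug = "norepinephrine")
  }

  # --- optional extra infection episodes -------------------------------------
  extra_adm <- NULL
  if (params$multi_episode_rate > 0) {
    multi <- which(runif(n) < params$multi_episode_rate)
    if (length(multi) > 0) {
      earlier <- runif(length(multi)) < 0.5
      # an episode after the index only makes sense for survivors
      earlier[death[multi] & !earlier] <- TRUE
      off <- ifelse(earlier,
                    -sample(500:1100, length(multi), replace = TRUE),
                    sample(400:800, length(multi), replace = TRUE))
      adm2 <- admit[multi] + off
      extra_adm <- tibble(patient_id = pid[multi], admit_date = adm2,
                          discharge_date = adm2 + 4L, icu_flag = FALSE,
                          died_in_hospital = FALSE)
      i <- sample.int(nrow(infect), length(multi), replace = TRUE)
      coded[[length(coded) + 1L]] <- tibble(patient_id = pid[multi], date = adm2,
                                            system = infect$system[i],
                                            code = infect$code[i])
      meds[[length(meds) + 1L]] <- tibble(patient_id = pid[multi], date = adm2,
                                          drug = sample(abx, length(multi), replace = TRUE))
    }
  }
  if (!is.null(extra_adm)) admissions <- bind_rows(admissions, extra_adm)

  # --- stress noise (breaks truth alignment; for phenotyper stress tests) ----
  if (params$evidence_noise_rate > 0) {
    ns <- stress_noise_events(pid, admit, discharge, creat_pre, bili_pre, plt_pre,
                              params$evidence_noise_rate, config)
    coded <- c(coded, list(ns$coded))
    meds <- c(meds, list(ns$meds))
    labs <- c(labs, list(ns$labs))
  }

  bundle <- ehr_bundle(
    patients = patients,
    admissions = admissions |> arrange(.data$patient_id, .data$admit_date),
    coded_events = list_rbind(coded) |> arrange(.data$patient_id, .data$date, .data$code),
    medication_events = list_rbind(meds) |> arrange(.data$patient_id, .data$date, .data$drug),
    labs = list_rbind(labs) |> arrange(.data$patient_id, .data$date, .data$analyte),
    genotypes = bind_cols(tibble(patient_id = pid), as_tibble(geno)),
    config = config
  )
  truth <- tibble(
    patient_id = pid, burden = burden, ldl_true = ldl_true, grs_true = grs_raw,
    p_sepsis = p_sep, sepsis = sepsis, criterion = criterion,
    p_icu = p_icu, icu_admission = icu, p_death = p_death, in_hospital_death = death
  )
  structure(list(bundle = bundle, truth = truth, params = params), class = "ehr_sim")
}

#' @export
print.ehr_sim <- function(x, ...) {
  cat("<ehr_sim> synthetic EHR cohort\n")
  print(x$bundle)
  cat(sprintf("  truth: %d patients, %d sepsis cases\n",
              nrow(x$truth), sum(x$truth$sepsis)))
  invisible(x)
}

empty_ehr_sim <- function(params, config) {
  empty_date <- as.Date(character(0))
  bundle <- ehr_bundle(
    patients = tibble(patient_id = character(0), sex = character(0),
                      birth_date = empty_date),
    admissions = tibble(patient_id = character(0), admit_date = empty_date,
                        discharge_date = empty_date, icu_flag = logical(0),
                        died_in_hospital = logical(0)),
    coded_events = tibble(patient_id = character(0), date = empty_date,
                          system = character(0), code = character(0)),
    medication_events = tibble(patient_id = character(0), date = empty_date,
                               drug = character(0), drug_class = character(0)),
    labs = tibble(patient_id = character(0), date = empty_date,
                  analyte = character(0), value = numeric(0), inpatient = logical(0)),
    genotypes = bind_cols(tibble(patient_id = character(0)),
                          as_tibble(matrix(numeric(0), nrow = 0,
                                           ncol = nrow(params$snp_weights),
                                           dimnames = list(NULL, params$snp_weights$rsid)))),
    config = config
  )
  truth <- tibble(patient_id = character(0), burden = integer(0),
                  ldl_true = numeric(0), grs_true = numeric(0),
                  p_sepsis = numeric(0), sepsis = logical(0), criterion = character(0),
                  p_icu = numeric(0), icu_admission = logical(0),
                  p_death = numeric(0), in_hospital_death = logical(0))
  structure(list(bundle = bundle, truth = truth, params = params), class = "ehr_sim")
}

stress_noise_events <- function(pid, admit, discharge, creat_pre, bili_pre,
                                plt_pre, rate, config) {
  n <- length(pid)
  pick <- function() which(runif(n) < rate)
  sev <- config_codes(config, "severe_sepsis_shock_codes")
  vent <- config_codes(config, "ventilation_codes")
  vaso <- config_codes(config, "vasopressor_admin_codes")
  icu <- config_codes(config, "icu_codes")
  coded <- list()
  add_codes <- function(tbl) {
    i <- pick()
    if (length(i) == 0) return(NULL)
    j <- sample.int(nrow(tbl), length(i), replace = TRUE)
    tibble(patient_id = pid[i], date = admit[i] + sample(-3:3, length(i), replace = TRUE),
           system = tbl$system[j], code = tbl$code[j])
  }
  coded <- purrr::compact(list(add_codes(sev), add_codes(vent), add_codes(vaso),
                               add_codes(icu)))
  i <- pick()
  meds <- if (length(i) > 0) {
    tibble(patient_id = pid[i],
           date = admit[i] + sample(-3:3, length(i), replace = TRUE),
           drug = sample(c("norepinephrine", "dopamine", "dobutamine"),
                         length(i), replace = TRUE))
  } else {
    tibble(patient_id = character(0), date = as.Date(character(0)), drug = character(0))
  }
  i <- pick()
  labs <- if (length(i) > 0) {
    an <- sample(c("creatinine", "bilirubin_total", "platelets"), length(i), replace = TRUE)
    base <- ifelse(an == "creatinine", creat_pre[i],
                   ifelse(an == "bilirubin_total", bili_pre[i], plt_pre[i]))
    tibble(patient_id = pid[i],
           date = admit[i] + sample(-3:3, length(i), replace = TRUE),
           analyte = an, value = pmax(base * runif(length(i), 0.3, 3), 1e-3),
           inpatient = TRUE)
  } else {
    tibble(patient_id = character(0), date = as.Date(character(0)),
           analyte = character(0), value = numeric(0), inpatient = logical(0))
  }
  list(coded = list_rbind(c(coded, list(tibble(patient_id = character(0),
                                               date = as.Date(character(0)),
                                               system = character(0),
                                               code = character(0))))),
       meds = meds, labs = labs)
}

#' Plant minimal sepsis evidence for one patient
#'
#' Inserts the minimal event set that satisfies exactly the requested sepsis
#' pathway in the day -1..+1 window of the patient's index (earliest)
#' admission.  The inverse of the phenotyper: evidence planted for a
#' criterion must be detected as that criterion.
#'
#' @param bundle An [ehr_bundle()].
#' @param patient_id A patient present in the bundle with at least one
#'   admission.
#' @param criterion One of `"explicit_code"`, `"cardiovascular"`,
#'   `"respiratory"`, `"renal"`, `"hepatic"`, `"hematologic"`.
#' @param config A [code_config][read_code_config].
#' @return The modified bundle.
#' @export
plant_sepsis_evidence <- function(bundle, patient_id, criterion,
                                  config = default_code_config()) {
  stopifnot(inherits(bundle, "ehr_bundle"), length(patient_id) == 1)
  if (!criterion %in% sepsis_criteria) {
    abort(paste0("unknown sepsis criterion: ", criterion,
                 " (expected one of ", paste(sepsis_criteria, collapse = ", "), ")"),
          class = "sepsisldl_param_error")
  }
  adm <- bundle$admissions |> filter(.data$patient_id == !!patient_id)
  if (nrow(adm) == 0) {
    abort(paste0("patient has no admission: ", patient_id),
          class = "sepsisldl_param_error")
  }
  adm <- adm |> arrange(.data$admit_date) |> slice(1)
  d0 <- adm$admit_date
  add_lab <- function(analyte, value, date, inpatient) {
    bundle$labs <<- bind_rows(bundle$labs,
                              tibble(patient_id = patient_id, date = date,
                                     analyte = analyte, value = value,
                                     inpatient = inpatient))
  }
  switch(criterion,
    explicit_code = {
      sev <- config_codes(config, "severe_sepsis_shock_codes")[1, ]
      bundle$coded_events <- bind_rows(bundle$coded_events,
                                       tibble(patient_id = patient_id, date = d0,
                                              system = sev$system, code = sev$code))
    },
    cardiovascular = {
      med <- tibble(patient_id = patient_id, date = d0, drug = "norepinephrine")
      med$drug_class <- drug_class_column(med$drug, config)
      bundle$medication_events <- bind_rows(bundle$medication_events, med)
    },
    respiratory = {
      vent <- config_codes(config, "ventilation_codes")[1, ]
      bundle$coded_events <- bind_rows(bundle$coded_events,
                                       tibble(patient_id = patient_id, date = d0,
                                              system = vent$system, code = vent$code))
      bundle$admissions <- bundle$admissions |>
        mutate(icu_flag = .data$icu_flag |
                 (.data$patient_id == !!patient_id & .data$admit_date == d0))
    },
    renal = {
      add_lab("creatinine", 0.8, d0 - 120L, FALSE)
      add_lab("creatinine", 1.6, d0 + 1L, TRUE)
    },
    hepatic = {
      add_lab("bilirubin_total", 0.6, d0 - 120L, FALSE)
      add_lab("bilirubin_total", 2.4, d0 + 1L, TRUE)
    },
    hematologic = {
      add_lab("platelets", 210, d0 - 120L, FALSE)
      add_lab("platelets", 95, d0 + 1L, TRUE)
    }
  )
  bundle
}
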