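# Hand-built micro-bundles for unit tests.  All dates are day-resolution;
# `D0` is the index admission date used throughout.

D0 <- as.Date("2015-06-01")

mk_patients <- function(ids, sex = "female", birth = as.Date("1950-01-15")) {
  tibble::tibble(patient_id = ids, sex = rep_len(sex, length(ids)),
                 birth_date = rep_len(as.Date(birth), length(ids)))
}

mk_admission <- function(id, admit = D0, los = 5, icu = FALSE, died = FALSE) {
  tibble::tibble(patient_id = id, admit_date = as.Date(admit),
                 discharge_date = as.Date(admit) + los, icu_flag = icu,
                 died_in_hospital = died)
}

mk_code <- function(id, day, code, system = "ICD9CM", ref = D0) {
  tibble::tibble(patient_id = id, date = as.Date(ref) + day,
                 system = system, code = code)
}

mk_med <- function(id, day, drug, ref = D0) {
  tibble::tibble(patient_id = id, date = as.Date(ref) + day, drug = drug)
}

mk_lab <- function(id, day, analyte, value, inpatient = FALSE, ref = D0) {
  tibble::tibble(patient_id = id, date = as.Date(ref) + day, analyte = analyte,
                 value = value, inpatient = inpatient)
}

empty_of <- function(proto) proto[0, ]

# a bundle with one patient, an index infection admission at D0
# (infection code day 0, antibiotic day -1) plus any extra events
toy_bundle <- function(codes = NULL, meds = NULL, labs = NULL,
                       admissions = NULL, patients = NULL,
                       id = "p1", icu = FALSE, died = FALSE,
                       config = default_code_config()) {
  patients <- patients %||% mk_patients(id)
  admissions <- admissions %||% mk_admission(id, icu = icu, died = died)
  codes <- dplyr::bind_rows(mk_code(id, 0, "486"), codes)
  meds <- dplyr::bind_rows(mk_med(id, -1, "vancomycin"), meds)
  labs <- labs %||% empty_of(mk_lab(id, 0, "ldl", 100))
  ehr_bundle(patients, admissions, codes, meds, labs, config = config)
}

toy_index_episode <- function(bundle, config = default_code_config()) {
  select_index_episodes(find_infection_episodes(bundle, config))
}

# replicate helper for parameter-recovery properties: simulate, run the
# measured arm of the pipeline, fit unadjusted and adjusted per-SD models
# for sepsis, and return the key quantities
replicate_sepsis_fit <- function(seed, n, direct_logor = 0) {
  sim <- generate_ehr_bundle(sim_params(n_patients = n, seed = seed,
                                        direct_ldl_logor_per_sd = direct_logor))
  tab <- measured_analysis_table(sim$bundle, lipid_covariates = FALSE)
  cm <- grep("^cm_", names(tab), value = TRUE)
  f0 <- as_tibble(fit_per_sd(tab, "sepsis", "ldl"))
  f1 <- as_tibble(suppressMessages(
    fit_per_sd(tab, "sepsis", "ldl", adjust = c("age", "sex", cm))
  ))
  tibble::tibble(seed = seed, n = nrow(tab),
                 unadj_log_or = f0$log_or, unadj_p = f0$p_value,
                 adj_log_or = f1$log_or, adj_ci_low = f1$ci_low,
                 adj_ci_high = f1$ci_high)
}
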