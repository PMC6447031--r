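#' Qualifying baseline LDL measurements for one patient
#'
#' A qualifying LDL measurement, relative to an index admission date, is one
#' that was (a) performed more than 1 year (strictly more than 365 days)
#' before the index admission; (b) not performed in hospital; (c) performed
#' at age 18 years or older; (d) not within 30 days (inclusive, either
#' direction) of a serum albumin measurement below 3.0 g/dL; and (e) dated
#' strictly before the first mention of statin therapy, if any.
#'
#' @param bundle An [ehr_bundle()].
#' @param patient_id A single patient id.
#' @param index_admit_date The index admission date (day 0).
#' @param config A [code_config][read_code_config].
#' @return The qualifying rows of the labs table (possibly empty).
#' @export
qualifying_ldl <- function(bundle, patient_id, index_admit_date,
                           config = default_code_config()) {
  stopifnot(length(patient_id) == 1, length(index_admit_date) == 1)
  episodes <- tibble(patient_id = patient_id,
                     admit_date = as.Date(index_admit_date))
  qualifying_ldl_all(bundle, episodes, config) |>
    select("patient_id", "date", "analyte", "value", "inpatient")
}

# vectorized qualifying-LDL rows for a set of (patient_id, admit_date) pairs
qualifying_ldl_all <- function(bundle, episodes, config = default_code_config()) {
  ldl <- bundle$labs |>
    filter(.data$analyte == "ldl") |>
    inner_join(episodes |> select("patient_id", "admit_date"), by = "patient_id") |>
    filter(as.integer(.data$admit_date - .data$date) > 365L,
           !.data$inpatient)
  if (nrow(ldl) == 0) return(ldl |> select(-"admit_date"))
  ldl <- ldl |>
    left_join(bundle$patients |> select("patient_id", "birth_date"), by = "patient_id") |>
    filter(completed_years(.data$birth_date, .data$date) >= 18L) |>
    select(-"birth_date")
  # albumin < 3 g/dL within +/- 30 days
  low_alb <- bundle$labs |>
    filter(.data$analyte == "albumin", .data$value < 3.0) |>
    select("patient_id", alb_date = "date")
  if (nrow(low_alb) > 0) {
    near_low <- ldl |>
      inner_join(low_alb, by = "patient_id", relationship = "many-to-many") |>
      filter(abs(as.integer(.data$date - .data$alb_date)) <= 30L) |>
      distinct(.data$patient_id, .data$date, .data$value)
    ldl <- ldl |> anti_join(near_low, by = c("patient_id", "date", "value"))
  }
  # strictly before first statin mention
  first_statin <- bundle$medication_events |>
    filter(has_drug_class(.data$drug_class, "statin")) |>
    summarise(statin_date = smin(.data$date), .by = "patient_id")
  if (nrow(first_statin) > 0) {
    ldl <- ldl |>
      left_join(first_statin, by = "patient_id") |>
      filter(is.na(.data$statin_date) | .data$date < .data$statin_date) |>
      select(-"statin_date")
  }
  ldl |> select(-"admit_date")
}

#' Baseline summary statistic: the median
#'
#' The baseline LDL is the median of a patient's qualifying measurements; an
#' even count yields the arithmetic mean of the two middle values.  Order of
#' the inputs is irrelevant.
#'
#' @param values Non-empty numeric vector.
#' @return The median.
#' @export
baseline_median <- function(values) {
  if (length(values) == 0) {
    abort("no qualifying measurements: no baseline can be formed",
          class = "sepsisldl_no_baseline")
  }
  median(values)
}

#' Per-patient baseline lipid profile
#'
#' For each index episode, computes the qualifying-LDL baseline (median of
#' qualifying values), the number of qualifying measurements, the date
#' of the latest qualifying measurement, medians of all HDL, triglyceride and
#' BMI values in the record, and the EHR length in years (span between the
#' patient's first and last recorded event, divided by 365.25).  Patients
#' with no qualifying LDL measurement are omitted.
#'
#' @param bundle An [ehr_bundle()].
#' @param episodes Index episodes (one row per patient, with `admit_date`).
#' @param config A [code_config][read_code_config].
#' @param lipid_covariates Also compute the all-record HDL / triglyceride /
#'   BMI medians and the EHR length (needed only for the extended
#'   adjustment set).
#' @return A tibble: `patient_id`, `ldl_baseline`, `n_qualifying`,
#'   `latest_qualifying_date`, and with `lipid_covariates` also
#'   `hdl_median`, `tg_median`, `bmi_median`, `ehr_length_years`.
#' @export
ldl_baselines <- function(bundle, episodes, config = default_code_config(),
                          lipid_covariates = TRUE) {
  qual <- qualifying_ldl_all(bundle,
                             episodes |> select("patient_id", "admit_date"),
                             config)
  base <- qual |>
    summarise(ldl_baseline = median(value),
              n_qualifying = dplyr::n(),
              latest_qualifying_date = smax(date),
              .by = "patient_id")
  if (lipid_covariates) {
    base <- base |> left_join(covariate_medians(bundle), by = "patient_id")
  }
  base |> arrange(.data$patient_id)
}

# per-patient record span in years over all event tables
ehr_length_years <- function(bundle) {
  bind_rows(
    bundle$admissions |> select("patient_id", date = "admit_date"),
    bundle$admissions |> select("patient_id", date = "discharge_date"),
    bundle$coded_events |> select("patient_id", "date"),
    bundle$medication_events |> select("patient_id", "date"),
    bundle$labs |> select("patient_id", "date")
  ) |>
    summarise(ehr_length_years = as.numeric(smax(date) - smin(date)) / 365.25,
              .by = "patient_id")
}

# per-patient anchor date for LDL-anchored index selection: the index episode
# must fall strictly more than one year after the patient's earliest
# otherwise-qualifying LDL measurement, so that at least one measurement
# qualifies relative to it.
ldl_anchor_dates <- function(bundle, config = default_code_config()) {
  # index-independent rules only (outpatient, adult, albumin, statin); the
  # one-year separation is enforced through the +365-day shift of the anchor.
  far_future <- smax(c(bundle$admissions$admit_date, bundle$labs$date)) + 1L
  pseudo <- bundle$labs |>
    filter(.data$analyte == "ldl") |>
    distinct(.data$patient_id) |>
    mutate(admit_date = far_future + 100000L)
  qualifying_ldl_all(bundle, pseudo, config) |>
    summarise(first_date = smin(.data$date), .by = "patient_id") |>
    mutate(anchor_date = .data$first_date + 365L) |>
    select("patient_id", "anchor_date")
}

#' Exclude episodes with evidence of severe chronic illness
#'
#' Drops index episodes whose patient carries any configured
#' exclusion-condition code (HIV, chronic kidney disease, liver disease,
#' chemotherapy) dated in the year before the index admission (days -365 to
#' -1 inclusive).
#'
#' @param episodes Index episodes.
#' @param bundle An [ehr_bundle()].
#' @param config A [code_config][read_code_config].
#' @return The retained episodes (a subset of `episodes`).
#' @export
apply_chronic_exclusions <- function(episodes, bundle, config = default_code_config()) {
  if (nrow(episodes) == 0) return(episodes)
  excl_codes <- config_codes(config, "exclusion_condition_codes")
  hits <- bundle$coded_events |>
    semi_join(excl_codes, by = c("system", "code")) |>
    inner_join(episodes |> select("patient_id", "admit_date"), by = "patient_id",
               relationship = "many-to-many") |>
    mutate(rel = as.integer(.data$date - .data$admit_date)) |>
    filter(.data$rel >= -365L, .data$rel <= -1L) |>
    distinct(.data$patient_id, .data$admit_date)
  episodes |> anti_join(hits, by = c("patient_id", "admit_date"))
}

#' LDL value closest to admission (sensitivity analysis)
#'
#' Returns the LDL measurement minimizing `|date - index_admit_date|` with no
#' qualification rules applied; ties are broken toward the earlier
#' measurement.  Used by the no-exclusions sensitivity analysis.
#'
#' @param bundle An [ehr_bundle()].
#' @param patient_id A single patient id.
#' @param index_admit_date The index admission date.
#' @return A single LDL value, or `NA_real_` if the patient has none.
#' @export
closest_to_admission_ldl <- function(bundle, patient_id, index_admit_date) {
  stopifnot(length(patient_id) == 1, length(index_admit_date) == 1)
  res <- closest_ldl_all(bundle, tibble(patient_id = patient_id,
                                        admit_date = as.Date(index_admit_date)))
  if (nrow(res) == 0) NA_real_ else res$ldl_closest
}

# vectorized closest-to-admission LDL over episodes
closest_ldl_all <- function(bundle, episodes) {
  bundle$labs |>
    filter(.data$analyte == "ldl") |>
    inner_join(episodes |> select("patient_id", "admit_date"), by = "patient_id") |>
    mutate(dist = abs(as.integer(.data$date - .data$admit_date))) |>
    arrange(.data$patient_id, .data$dist, .data$date) |>
    distinct(.data$patient_id, .keep_all = TRUE) |>
    select("patient_id", ldl_closest = "value")
}
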