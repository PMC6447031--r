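#' Identify adult infection episodes
#'
#' An infection episode is a (patient, admission) pair with at least one
#' qualifying infection billing code dated within the admission
#' (`admit_date` to `discharge_date`, inclusive) and at least one antibiotic
#' record on relative day -1, 0 or +1 of admission.  Patients younger than 18
#' years at admission are excluded.  The admission day is day 0 and relative
#' days are whole calendar days.
#'
#' @param bundle An [ehr_bundle()].
#' @param config A [code_config][read_code_config].
#' @return A tibble with one row per candidate episode: `patient_id`,
#'   `admit_date`, `discharge_date`, `icu_flag`, `died_in_hospital`,
#'   `infection_code`, `infection_system`, `infection_date`,
#'   `antibiotic_day` (the earliest qualifying day in -1..+1) and
#'   `age_at_admission` (completed years).
#' @export
find_infection_episodes <- function(bundle, config = default_code_config()) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  adm <- bundle$admissions
  empty <- tibble(patient_id = character(0), admit_date = as.Date(character(0)),
                  discharge_date = as.Date(character(0)), icu_flag = logical(0),
                  died_in_hospital = logical(0), infection_code = character(0),
                  infection_system = character(0),
                  infection_date = as.Date(character(0)),
                  antibiotic_day = integer(0), age_at_admission = integer(0))
  if (nrow(adm) == 0) return(empty)

  inf_codes <- config_codes(config, "infection_codes")
  inf_events <- bundle$coded_events |>
    semi_join(inf_codes, by = c("system", "code"))
  if (nrow(inf_events) == 0) return(empty)

  # attribute infection codes to admissions: date within [admit, discharge]
  cand <- adm |>
    inner_join(inf_events, by = "patient_id", relationship = "many-to-many") |>
    filter(.data$date >= .data$admit_date, .data$date <= .data$discharge_date) |>
    # one evidence code per admission, deterministically (earliest date, then code)
    arrange(.data$patient_id, .data$admit_date, .data$date, .data$code) |>
    distinct(.data$patient_id, .data$admit_date, .keep_all = TRUE) |>
    rename(infection_code = "code", infection_system = "system",
           infection_date = "date")

  abx <- bundle$medication_events |>
    filter(has_drug_class(.data$drug_class, "antibiotic")) |>
    select("patient_id", abx_date = "date")
  if (nrow(abx) == 0) return(empty)
  cand <- cand |>
    inner_join(abx, by = "patient_id", relationship = "many-to-many") |>
    mutate(rel_day = as.integer(.data$abx_date - .data$admit_date)) |>
    filter(.data$rel_day >= -1L, .data$rel_day <= 1L) |>
    arrange(.data$patient_id, .data$admit_date, .data$rel_day) |>
    distinct(.data$patient_id, .data$admit_date, .keep_all = TRUE) |>
    rename(antibiotic_day = "rel_day") |>
    select(-"abx_date")

  cand |>
    left_join(bundle$patients |> select("patient_id", "birth_date"), by = "patient_id") |>
    mutate(age_at_admission = completed_years(.data$birth_date, .data$admit_date)) |>
    filter(.data$age_at_admission >= 18L) |>
    select(-"birth_date") |>
    arrange(.data$patient_id, .data$admit_date)
}

# completed years between two Dates (birthday arithmetic, no fractional years)
completed_years <- function(from, to) {
  fy <- as.POSIXlt(from); ty <- as.POSIXlt(to)
  yrs <- ty$year - fy$year
  before_birthday <- (ty$mon < fy$mon) | (ty$mon == fy$mon & ty$mday < fy$mday)
  as.integer(yrs - before_birthday)
}

#' Select each patient's index infection episode
#'
#' Without an LDL anchor, the index episode is the patient's first episode
#' (earliest `admit_date`; ties broken by infection code, lexicographically).
#' With `ldl_anchor_dates` supplied, the index is the first episode whose
#' admission is strictly after that patient's latest qualifying LDL
#' measurement date; patients whose episodes all precede the anchor (or who
#' have no anchor) are dropped.
#'
#' @param episodes Output of [find_infection_episodes()].
#' @param ldl_anchor_dates Optional tibble with `patient_id` and
#'   `anchor_date` (each patient's latest qualifying LDL date).
#' @return A tibble with at most one row per patient, a subset of `episodes`.
#' @export
select_index_episodes <- function(episodes, ldl_anchor_dates = NULL) {
  if (nrow(episodes) == 0) return(episodes)
  if (!is.null(ldl_anchor_dates)) {
    stopifnot(all(c("patient_id", "anchor_date") %in% names(ldl_anchor_dates)))
    episodes <- episodes |>
      inner_join(ldl_anchor_dates |> select("patient_id", "anchor_date"),
                 by = "patient_id") |>
      filter(.data$admit_date > .data$anchor_date) |>
      select(-"anchor_date")
  }
  episodes |>
    arrange(.data$patient_id, .data$admit_date, .data$infection_code) |>
    distinct(.data$patient_id, .keep_all = TRUE)
}
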