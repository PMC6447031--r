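#' Organ-dysfunction lab baselines
#'
#' Baselines are per-analyte extrema over the span from 1 year before the
#' index admission to hospital discharge (inclusive, and including values in
#' the day -1..+1 sepsis window): the lowest creatinine, the lowest total
#' bilirubin and the highest platelet count.  An absent analyte yields an
#' absent (`NA`) baseline, against which the corresponding criterion
#' evaluates false.
#'
#' @param bundle An [ehr_bundle()].
#' @param episodes Index episodes (`patient_id`, `admit_date`,
#'   `discharge_date`).
#' @return A tibble: `patient_id`, `creatinine_baseline`,
#'   `bilirubin_baseline`, `platelet_baseline` (one row per episode patient;
#'   `NA` where the analyte is absent).
#' @export
compute_lab_baselines <- function(bundle, episodes) {
  span <- bundle$labs |>
    filter(.data$analyte %in% c("creatinine", "bilirubin_total", "platelets")) |>
    inner_join(episodes |> select("patient_id", "admit_date", "discharge_date"),
               by = "patient_id") |>
    filter(.data$date >= .data$admit_date - 365L,
           .data$date <= .data$discharge_date)
  ext <- span |>
    summarise(
      creatinine_baseline = suppressWarnings(min(value[analyte == "creatinine"])),
      bilirubin_baseline = suppressWarnings(min(value[analyte == "bilirubin_total"])),
      platelet_baseline = suppressWarnings(max(value[analyte == "platelets"])),
      .by = "patient_id"
    ) |>
    mutate(across(ends_with("_baseline"),
                  function(x) ifelse(is.finite(x), x, NA_real_)))
  episodes |>
    distinct(.data$patient_id) |>
    left_join(ext, by = "patient_id")
}

#' Organ-dysfunction criteria on window labs
#'
#' Pure threshold rules applied to the lab values observed in the day -1..+1
#' window, judged against the patient's baseline:
#' * renal failure: doubling or greater of the baseline (lowest) creatinine —
#'   `max(window) >= 2 * baseline`;
#' * hepatic failure: some window total bilirubin at least 2.0 mg/dL that has
#'   also at least doubled from the baseline (lowest) bilirubin;
#' * hematologic failure: some window platelet count below 100 (10^3/uL)
#'   representing at least a 50% decline from a baseline (highest) count that
#'   was itself at least 100.
#'
#' All thresholds are inclusive ("doubling or greater", "at least a 50%
#' decline").  An absent (`NA`) or empty input yields `FALSE`.
#'
#' @param window_creatinine,window_bilirubin,window_platelets Numeric vectors
#'   of values observed in the window (possibly empty).
#' @param baseline The per-analyte baseline (see [compute_lab_baselines()]).
#' @return A single logical.
#' @examples
#' renal_failure(c(1.0, 1.6), baseline = 0.8)        # TRUE
#' hepatic_failure(2.4, baseline = 0.6)              # TRUE
#' hematologic_failure(95, baseline = 210)           # TRUE
#' hematologic_failure(40, baseline = 90)            # FALSE: baseline < 100
#' @export
renal_failure <- function(window_creatinine, baseline) {
  if (is_absent(baseline) || baseline <= 0 || length(window_creatinine) == 0) return(FALSE)
  max(window_creatinine) >= 2 * baseline
}

#' @rdname renal_failure
#' @export
hepatic_failure <- function(window_bilirubin, baseline) {
  if (is_absent(baseline) || length(window_bilirubin) == 0) return(FALSE)
  any(window_bilirubin >= 2.0 & window_bilirubin >= 2 * baseline)
}

#' @rdname renal_failure
#' @export
hematologic_failure <- function(window_platelets, baseline) {
  if (is_absent(baseline) || length(window_platelets) == 0) return(FALSE)
  baseline >= 100 && any(window_platelets < 100 & window_platelets <= 0.5 * baseline)
}

is_absent <- function(x) length(x) == 0 || is.na(x)

#' Medication/code-based organ-dysfunction criteria for one episode
#'
#' Cardiovascular failure: a norepinephrine record in the day -1..+1 window,
#' or a dopamine/dobutamine record in the window together with a billing code
#' for administration of a vasopressor in the window.  Respiratory failure: a
#' ventilation code in the window together with ICU admission (the
#' admission-level flag, or an ICU marker code in the window).
#'
#' @param bundle An [ehr_bundle()].
#' @param episode A single episode row (`patient_id`, `admit_date`, and for
#'   respiratory failure `icu_flag`).
#' @param config A [code_config][read_code_config].
#' @return A single logical.
#' @export
cardiovascular_failure <- function(bundle, episode, config = default_code_config()) {
  stopifnot(nrow(episode) == 1)
  flags <- phenotype_flags(bundle, episode, config)
  flags$cardiovascular
}

#' @rdname cardiovascular_failure
#' @export
respiratory_failure <- function(bundle, episode, config = default_code_config()) {
  stopifnot(nrow(episode) == 1)
  flags <- phenotype_flags(bundle, episode, config)
  flags$respiratory
}

#' Classify index infection episodes for sepsis
#'
#' Applies the rule-based sepsis algorithm to each index episode: sepsis is
#' called if an explicit severe-sepsis/septic-shock code is present in the
#' day -1..+1 window, or if any of the five organ-dysfunction criteria
#' (cardiovascular, respiratory, renal, hepatic, hematologic) is met on
#' window evidence judged against the 1-year-to-discharge lab baselines.
#' ICU admission and in-hospital death are copied from the index admission.
#'
#' @param bundle An [ehr_bundle()].
#' @param episodes Index episodes (from [select_index_episodes()]).
#' @param config A [code_config][read_code_config].
#' @param evidence If `TRUE` (default), attach an `evidence` list-column of
#'   human-readable evidence strings for each flagged pathway.
#' @return A tibble with one row per episode: `patient_id`, `admit_date`,
#'   `explicit_code`, the five organ flags, `sepsis` (their disjunction),
#'   `icu_admission`, `in_hospital_death`, and optionally `evidence`.
#' @export
classify_sepsis <- function(bundle, episodes, config = default_code_config(),
                            evidence = TRUE) {
  flags <- phenotype_flags(bundle, episodes, config, evidence = evidence)
  out <- episodes |>
    select("patient_id", "admit_date", "icu_flag", "died_in_hospital") |>
    left_join(flags, by = c("patient_id", "admit_date")) |>
    mutate(across(c("explicit_code", "cardiovascular", "respiratory",
                    "renal", "hepatic", "hematologic"),
                  function(x) replace_na(x, FALSE)),
           sepsis = .data$explicit_code | .data$cardiovascular |
             .data$respiratory | .data$renal | .data$hepatic | .data$hematologic) |>
    rename(icu_admission = "icu_flag", in_hospital_death = "died_in_hospital") |>
    relocate("sepsis", .after = "hematologic") |>
    relocate("icu_admission", "in_hospital_death", .after = "sepsis")
  if (evidence && !"evidence" %in% names(out)) out$evidence <- list(character(0))
  out
}

# vectorized flag computation shared by classify_sepsis and the scalar ops
phenotype_flags <- function(bundle, episodes, config, evidence = FALSE) {
  if (!"discharge_date" %in% names(episodes)) {
    episodes <- episodes |>
      left_join(bundle$admissions |> select("patient_id", "admit_date", "discharge_date"),
                by = c("patient_id", "admit_date"))
  }
  if (!"icu_flag" %in% names(episodes)) {
    episodes <- episodes |>
      left_join(bundle$admissions |>
                  select("patient_id", "admit_date", "icu_flag"),
                by = c("patient_id", "admit_date"))
  }
  key <- episodes |> select("patient_id", "admit_date", "discharge_date", "icu_flag")

  win_codes <- bundle$coded_events |>
    inner_join(key |> select("patient_id", "admit_date"), by = "patient_id",
               relationship = "many-to-many") |>
    mutate(rel = as.integer(.data$date - .data$admit_date)) |>
    filter(.data$rel >= -1L, .data$rel <= 1L)
  code_flag <- function(entry) {
    win_codes |>
      semi_join(config_codes(config, entry), by = c("system", "code")) |>
      summarise(ev = paste0(.data$code[1], "@", .data$date[1]),
                .by = c("patient_id", "admit_date"))
  }
  explicit <- code_flag("severe_sepsis_shock_codes")
  vent <- code_flag("ventilation_codes")
  vaso_admin <- code_flag("vasopressor_admin_codes")
  icu_code <- code_flag("icu_codes")

  win_meds <- bundle$medication_events |>
    inner_join(key |> select("patient_id", "admit_date"), by = "patient_id",
               relationship = "many-to-many") |>
    mutate(rel = as.integer(.data$date - .data$admit_date)) |>
    filter(.data$rel >= -1L, .data$rel <= 1L)
  norepi <- win_meds |>
    filter(has_drug_class(.data$drug_class, "norepinephrine")) |>
    summarise(ev = paste0(.data$drug[1], "@", .data$date[1]),
              .by = c("patient_id", "admit_date"))
  dopa_dobu <- win_meds |>
    filter(has_drug_class(.data$drug_class, "dopamine") |
             has_drug_class(.data$drug_class, "dobutamine")) |>
    summarise(ev = paste0(.data$drug[1], "@", .data$date[1]),
              .by = c("patient_id", "admit_date"))

  baselines <- compute_lab_baselines(bundle, key)
  win_labs <- bundle$labs |>
    filter(.data$analyte %in% c("creatinine", "bilirubin_total", "platelets")) |>
    inner_join(key |> select("patient_id", "admit_date"), by = "patient_id",
               relationship = "many-to-many") |>
    mutate(rel = as.integer(.data$date - .data$admit_date)) |>
    filter(.data$rel >= -1L, .data$rel <= 1L) |>
    left_join(baselines, by = "patient_id")
  renal_hits <- win_labs |>
    filter(.data$analyte == "creatinine", !is.na(.data$creatinine_baseline),
           .data$creatinine_baseline > 0,
           .data$value >= 2 * .data$creatinine_baseline) |>
    arrange(desc(.data$value)) |>
    distinct(.data$patient_id, .data$admit_date, .keep_all = TRUE) |>
    transmute(.data$patient_id, .data$admit_date,
              ev = sprintf("creatinine %.2f vs baseline %.2f",
                           .data$value, .data$creatinine_baseline))
  hepatic_hits <- win_labs |>
    filter(.data$analyte == "bilirubin_total", !is.na(.data$bilirubin_baseline),
           .data$value >= 2.0, .data$value >= 2 * .data$bilirubin_baseline) |>
    arrange(desc(.data$value)) |>
    distinct(.data$patient_id, .data$admit_date, .keep_all = TRUE) |>
    transmute(.data$patient_id, .data$admit_date,
              ev = sprintf("bilirubin %.2f vs baseline %.2f",
                           .data$value, .data$bilirubin_baseline))
  heme_hits <- win_labs |>
    filter(.data$analyte == "platelets", !is.na(.data$platelet_baseline),
           .data$platelet_baseline >= 100, .data$value < 100,
           .data$value <= 0.5 * .data$platelet_baseline) |>
    arrange(.data$value) |>
    distinct(.data$patient_id, .data$admit_date, .keep_all = TRUE) |>
    transmute(.data$patient_id, .data$admit_date,
              ev = sprintf("platelets %.0f vs baseline %.0f",
                           .data$value, .data$platelet_baseline))

  flag_join <- function(out, hits, flag, evname) {
    out |>
      left_join(hits |> mutate("{flag}" := TRUE) |>
                  rename("{evname}" := "ev"),
                by = c("patient_id", "admit_date")) |>
      mutate("{flag}" := replace_na(.data[[flag]], FALSE))
  }
  out <- key |>
    flag_join(explicit, "explicit_code", "ev_explicit") |>
    flag_join(norepi, "has_norepi", "ev_norepi") |>
    flag_join(dopa_dobu, "has_dopa", "ev_dopa") |>
    flag_join(vaso_admin, "has_vaso_code", "ev_vaso") |>
    flag_join(vent, "has_vent", "ev_vent") |>
    flag_join(icu_code, "has_icu_code", "ev_icu") |>
    flag_join(renal_hits, "renal", "ev_renal") |>
    flag_join(hepatic_hits, "hepatic", "ev_hepatic") |>
    flag_join(heme_hits, "hematologic", "ev_heme") |>
    mutate(
      cardiovascular = .data$has_norepi | (.data$has_dopa & .data$has_vaso_code),
      respiratory = .data$has_vent & (replace_na(.data$icu_flag, FALSE) | .data$has_icu_code)
    )
  if (evidence) {
    out$evidence <- purrr::pmap(
      list(out$explicit_code, out$ev_explicit,
           out$cardiovascular, out$ev_norepi, out$ev_dopa, out$ev_vaso,
           out$respiratory, out$ev_vent,
           out$renal, out$ev_renal, out$hepatic, out$ev_hepatic,
           out$hematologic, out$ev_heme),
      function(ex, eex, cv, en, ed, eva, rs, evt, rn, ern, hp, ehp, hm, ehm) {
        ev <- character(0)
        if (ex) ev <- c(ev, paste0("explicit_code: ", eex))
        if (cv) ev <- c(ev, paste0("cardiovascular: ",
                                   paste(stats::na.omit(c(en, ed, eva)), collapse = " + ")))
        if (rs) ev <- c(ev, paste0("respiratory: ", evt, " + ICU"))
        if (rn) ev <- c(ev, paste0("renal: ", ern))
        if (hp) ev <- c(ev, paste0("hepatic: ", ehp))
        if (hm) ev <- c(ev, paste0("hematologic: ", ehm))
        ev
      })
  }
  out |>
    select("patient_id", "admit_date", "explicit_code", "cardiovascular",
           "respiratory", "renal", "hepatic", "hematologic", any_of("evidence"))
}
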