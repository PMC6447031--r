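# Independent brute-force reference for the sepsis phenotyper: a direct
# per-patient transcription of the decision rules, no joins, no
# vectorization across patients.  Kept deliberately separate from the
# package implementation so the two can disagree.

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_classify <- function(bundle, episodes, config = default_code_config()) {
  pair_set <- function(entry) {
    lst <- config[[entry]]
    unlist(lapply(names(lst), function(sys) paste(sys, lst[[sys]])), use.names = FALSE)
  }
  severe_set <- pair_set("severe_sepsis_shock_codes")
  vent_set <- pair_set("ventilation_codes")
  vaso_set <- pair_set("vasopressor_admin_codes")
  icu_set <- pair_set("icu_codes")
  norm <- function(x) gsub("\\s+", " ", trimws(tolower(x)))
  norepi_names <- norm(config$norepinephrine_names)
  dopa_names <- norm(config$dopamine_names)
  dobu_names <- norm(config$dobutamine_names)

  codes_by <- split(bundle$coded_events, bundle$coded_events$patient_id)
  meds_by <- split(bundle$medication_events, bundle$medication_events$patient_id)
  labs_by <- split(bundle$labs, bundle$labs$patient_id)

  out <- vector("list", nrow(episodes))
  for (i in seq_len(nrow(episodes))) {
    pid <- episodes$patient_id[i]
    admit <- episodes$admit_date[i]
    disc <- episodes$discharge_date[i]
    icu <- isTRUE(episodes$icu_flag[i])

    codes <- codes_by[[pid]]
    in_win_code <- character(0)
    if (!is.null(codes)) {
      rel <- as.integer(codes$date - admit)
      keep <- rel >= -1 & rel <= 1
      in_win_code <- paste(codes$system[keep], codes$code[keep])
    }
    explicit <- any(in_win_code %in% severe_set)
    vent_in <- any(in_win_code %in% vent_set)
    vaso_in <- any(in_win_code %in% vaso_set)
    icu_code_in <- any(in_win_code %in% icu_set)

    meds <- meds_by[[pid]]
    norepi_in <- dopa_in <- dobu_in <- FALSE
    if (!is.null(meds)) {
      rel <- as.integer(meds$date - admit)
      d <- norm(meds$drug[rel >= -1 & rel <= 1])
      norepi_in <- any(d %in% norepi_names)
      dopa_in <- any(d %in% dopa_names)
      dobu_in <- any(d %in% dobu_names)
    }
    cardiovascular <- norepi_in || ((dopa_in || dobu_in) && vaso_in)
    respiratory <- vent_in && (icu || icu_code_in)

    labs <- labs_by[[pid]]
    renal <- hepatic <- hematologic <- FALSE
    if (!is.null(labs)) {
      span <- labs$date >= admit - 365 & labs$date <= disc
      rel <- as.integer(labs$date - admit)
      win <- rel >= -1 & rel <= 1
      cre_base <- labs$value[span & labs$analyte == "creatinine"]
      cre_win <- labs$value[win & labs$analyte == "creatinine"]
      if (length(cre_base) > 0 && length(cre_win) > 0) {
        b <- min(cre_base)
        renal <- b > 0 && max(cre_win) >= 2 * b
      }
      bil_base <- labs$value[span & labs$analyte == "bilirubin_total"]
      bil_win <- labs$value[win & labs$analyte == "bilirubin_total"]
      if (length(bil_base) > 0 && length(bil_win) > 0) {
        b <- min(bil_base)
        hepatic <- any(bil_win >= 2.0 & bil_win >= 2 * b)
      }
      plt_base <- labs$value[span & labs$analyte == "platelets"]
      plt_win <- labs$value[win & labs$analyte == "platelets"]
      if (length(plt_base) > 0 && length(plt_win) > 0) {
        b <- max(plt_base)
        hematologic <- b >= 100 && any(plt_win < 100 & plt_win <= 0.5 * b)
      }
    }
    out[[i]] <- data.frame(
      patient_id = pid, explicit_code = explicit,
      cardiovascular = cardiovascular, respiratory = respiratory,
      renal = renal, hepatic = hepatic, hematologic = hematologic,
      sepsis = explicit || cardiovascular || respiratory || renal ||
        hepatic || hematologic
    )
  }
  do.call(rbind, out)
}
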