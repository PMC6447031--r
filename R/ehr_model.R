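#' The EHR bundle: five linked longitudinal tables
#'
#' An `ehr_bundle` is the lingua franca of the pipeline: a validated list of
#' five tibbles (plus an optional genotype dosage table) with day-resolution
#' dates and canonical lab units.
#'
#' Table schemas (all columns required unless noted):
#' \describe{
#'   \item{patients}{`patient_id` (character, unique), `sex` (`"female"`/`"male"`),
#'     `birth_date` (Date).}
#'   \item{admissions}{`patient_id`, `admit_date`, `discharge_date` (Dates,
#'     `discharge_date >= admit_date`), `icu_flag`, `died_in_hospital`
#'     (logical, scoped to this admission).}
#'   \item{coded_events}{`patient_id`, `date`, `system`
#'     (`"ICD9CM"`/`"ICD10"`/`"PROC"`), `code` (non-empty character).}
#'   \item{medication_events}{`patient_id`, `date`, `drug` (normalized
#'     lowercase name); `drug_class` is derived deterministically from `drug`
#'     via [classify_drug()] and stored as a `"+"`-joined character column.}
#'   \item{labs}{`patient_id`, `date`, `analyte` (one of `ldl`, `hdl`,
#'     `triglycerides`, `albumin`, `creatinine`, `bilirubin_total`,
#'     `platelets`, `bmi`), `value` (> 0, canonical unit), `inpatient`
#'     (logical).}
#' }
#'
#' Canonical lab units are mg/dL for lipids, creatinine and total bilirubin;
#' g/dL for albumin; 10^3/uL for platelets; kg/m^2 for BMI.  Readers accept an
#' optional `unit` column and convert (see [canonicalize_labs()]).
#'
#' @param patients,admissions,coded_events,medication_events,labs Data frames
#'   following the schemas above.
#' @param genotypes Optional data frame: `patient_id` plus one numeric dosage
#'   column per SNP (values in \[0, 2\] or `NA`).
#' @param config A [code_config][read_code_config] used to derive
#'   `drug_class`; defaults to the shipped configuration.
#' @param validate If `TRUE` (default), enforce all schema and integrity
#'   invariants; violations raise classed errors.
#' @return An `ehr_bundle` object.
#' @seealso [read_ehr_bundle()], [write_ehr_bundle()], [generate_ehr_bundle()]
#' @export
ehr_bundle <- function(patients, admissions, coded_events, medication_events,
                       labs, genotypes = NULL, config = default_code_config(),
                       validate = TRUE) {
  medication_events <- as_tibble(medication_events)
  if (nrow(medication_events) > 0) {
    medication_events$drug <- normalize_drug(medication_events$drug)
    medication_events$drug_class <- drug_class_column(medication_events$drug, config)
  } else if (!"drug_class" %in% names(medication_events)) {
    medication_events$drug_class <- character(0)
  }
  b <- structure(
    list(
      patients = as_tibble(patients),
      admissions = as_tibble(admissions),
      coded_events = as_tibble(coded_events),
      medication_events = medication_events,
      labs = as_tibble(labs),
      genotypes = if (!is.null(genotypes)) as_tibble(genotypes) else NULL
    ),
    class = "ehr_bundle"
  )
  if (validate) validate_ehr_bundle(b)
  b
}

#' @export
print.ehr_bundle <- function(x, ...) {
  cat("<ehr_bundle>\n")
  cat(sprintf("  patients:          %d\n", nrow(x$patients)))
  cat(sprintf("  admissions:        %d\n", nrow(x$admissions)))
  cat(sprintf("  coded_events:      %d\n", nrow(x$coded_events)))
  cat(sprintf("  medication_events: %d\n", nrow(x$medication_events)))
  cat(sprintf("  labs:              %d\n", nrow(x$labs)))
  if (!is.null(x$genotypes)) {
    cat(sprintf("  genotypes:         %d patients x %d SNPs\n",
                nrow(x$genotypes), ncol(x$genotypes) - 1L))
  }
  invisible(x)
}

lab_analytes <- c("ldl", "hdl", "triglycerides", "albumin", "creatinine",
                  "bilirubin_total", "platelets", "bmi")

canonical_units <- c(
  ldl = "mg/dL", hdl = "mg/dL", triglycerides = "mg/dL", creatinine = "mg/dL",
  bilirubin_total = "mg/dL", albumin = "g/dL", platelets = "1e3/uL", bmi = "kg/m2"
)

#' Validate an EHR bundle
#'
#' Checks table schemas, enum values, date ordering and referential integrity
#' (every event's `patient_id` must appear in `patients`, and every patient's
#' `birth_date` must precede all of that patient's events).
#'
#' @param bundle An [ehr_bundle()].
#' @return `bundle`, invisibly, if valid; otherwise a classed error
#'   (`sepsisldl_schema_error` or `sepsisldl_integrity_error`).
#' @export
validate_ehr_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  schemas <- list(
    patients = c("patient_id", "sex", "birth_date"),
    admissions = c("patient_id", "admit_date", "discharge_date", "icu_flag",
                   "died_in_hospital"),
    coded_events = c("patient_id", "date", "system", "code"),
    medication_events = c("patient_id", "date", "drug", "drug_class"),
    labs = c("patient_id", "date", "analyte", "value", "inpatient")
  )
  for (tab in names(schemas)) {
    miss <- setdiff(schemas[[tab]], names(bundle[[tab]]))
    if (length(miss) > 0) {
      abort(sprintf("table '%s' is missing column(s): %s", tab,
                    paste(miss, collapse = ", ")),
            class = "sepsisldl_schema_error")
    }
  }
  date_cols <- list(patients = "birth_date", admissions = c("admit_date", "discharge_date"),
                    coded_events = "date", medication_events = "date", labs = "date")
  for (tab in names(date_cols)) {
    for (col in date_cols[[tab]]) {
      if (!inherits(bundle[[tab]][[col]], "Date")) {
        abort(sprintf("column '%s' of table '%s' must be a Date", col, tab),
              class = "sepsisldl_schema_error")
      }
    }
  }
  p <- bundle$patients
  if (anyDuplicated(p$patient_id)) {
    abort("duplicate patient_id in patients table", class = "sepsisldl_integrity_error")
  }
  if (nrow(p) > 0 && !all(p$sex %in% c("female", "male"))) {
    abort("patients$sex must be 'female' or 'male'", class = "sepsisldl_schema_error")
  }
  a <- bundle$admissions
  if (nrow(a) > 0 && any(a$discharge_date < a$admit_date)) {
    abort("admissions with discharge_date before admit_date", class = "sepsisldl_integrity_error")
  }
  ce <- bundle$coded_events
  if (nrow(ce) > 0) {
    if (!all(ce$system %in% c("ICD9CM", "ICD10", "PROC"))) {
      abort("coded_events$system must be ICD9CM, ICD10 or PROC",
            class = "sepsisldl_schema_error")
    }
    if (any(is.na(ce$code) | ce$code == "")) {
      abort("coded_events$code must be non-empty", class = "sepsisldl_schema_error")
    }
  }
  lb <- bundle$labs
  if (nrow(lb) > 0) {
    if (!all(lb$analyte %in% lab_analytes)) {
      abort(sprintf("unknown lab analyte(s): %s",
                    paste(setdiff(unique(lb$analyte), lab_analytes), collapse = ", ")),
            class = "sepsisldl_schema_error")
    }
    if (any(!is.finite(lb$value) | lb$value <= 0)) {
      abort("labs$value must be finite and > 0", class = "sepsisldl_schema_error")
    }
  }
  known <- p$patient_id
  for (tab in c("admissions", "coded_events", "medication_events", "labs")) {
    orphan <- setdiff(unique(bundle[[tab]]$patient_id), known)
    if (length(orphan) > 0) {
      abort(sprintf("table '%s' references unknown patient_id(s): %s", tab,
                    paste(head(orphan, 5), collapse = ", ")),
            class = "sepsisldl_integrity_error")
    }
  }
  if (!is.null(bundle$genotypes)) {
    orphan <- setdiff(unique(bundle$genotypes$patient_id), known)
    if (length(orphan) > 0) {
      abort("genotypes reference unknown patient_id(s)", class = "sepsisldl_integrity_error")
    }
  }
  # birth precedes all events
  ev_min <- bind_rows(
    bundle$admissions |> select("patient_id", date = "admit_date"),
    bundle$coded_events |> select("patient_id", "date"),
    bundle$medication_events |> select("patient_id", "date"),
    bundle$labs |> select("patient_id", "date")
  ) |>
    summarise(first_event = smin(.data$date), .by = "patient_id") |>
    left_join(p |> select("patient_id", "birth_date"), by = "patient_id")
  bad <- ev_min |> filter(.data$first_event <= .data$birth_date)
  if (nrow(bad) > 0) {
    abort(sprintf("events dated on/before birth_date for patient(s): %s",
                  paste(head(bad$patient_id, 5), collapse = ", ")),
          class = "sepsisldl_integrity_error")
  }
  invisible(bundle)
}

#' Canonicalize lab units
#'
#' Converts a labs table carrying an optional `unit` column into canonical
#' units and drops the `unit` column.  Supported conversions: total bilirubin
#' umol/L -> mg/dL (divide by 17.104) and albumin g/L -> g/dL (divide by 10).
#' Values already in canonical units pass through unchanged, so the operation
#' is idempotent.
#'
#' @param labs A labs tibble, optionally with a `unit` column.
#' @return The labs tibble in canonical units, without a `unit` column.
#' @examples
#' canonicalize_labs(tibble::tibble(
#'   patient_id = "p1", date = as.Date("2010-01-01"),
#'   analyte = "bilirubin_total", value = 34.208, inpatient = FALSE,
#'   unit = "umol/L"
#' ))$value  # 2.0 mg/dL
#' @export
canonicalize_labs <- function(labs) {
  labs <- as_tibble(labs)
  if (!"unit" %in% names(labs)) return(labs)
  unit <- trimws(labs$unit)
  value <- labs$value
  canon <- unname(canonical_units[labs$analyte])
  is_canon <- is.na(unit) | unit == "" | unit == canon
  conv_bili <- !is_canon & labs$analyte == "bilirubin_total" & unit %in% c("umol/L", "µmol/L")
  conv_alb <- !is_canon & labs$analyte == "albumin" & unit == "g/L"
  unknown <- !is_canon & !conv_bili & !conv_alb
  if (any(unknown)) {
    abort(sprintf("unsupported unit(s): %s",
                  paste(unique(paste0(labs$analyte[unknown], " [", unit[unknown], "]")),
                        collapse = ", ")),
          class = "sepsisldl_schema_error")
  }
  value[conv_bili] <- value[conv_bili] / 17.104
  value[conv_alb] <- value[conv_alb] / 10
  labs$value <- value
  labs$unit <- NULL
  labs
}

#' Classify a drug name
#'
#' Deterministic, case- and whitespace-insensitive lookup of a medication
#' name against the configured name lists.  A name can belong to several
#' classes; unknown names map to `"other"`.
#'
#' @param name Character vector of drug names.
#' @param config A [code_config][read_code_config].
#' @return For a single name, a character vector (the class set); for a
#'   vector of names, a list of such sets.
#' @examples
#' classify_drug("Norepinephrine Bitartrate")  # "norepinephrine"
#' classify_drug("atorvastatin")               # "statin"
#' classify_drug("gibberish-xyz")              # "other"
#' @export
classify_drug <- function(name, config = default_code_config()) {
  stopifnot(length(name) >= 1, !any(is.na(name)), all(nzchar(trimws(name))))
  sets <- drug_class_sets(normalize_drug(name), config)
  if (length(name) == 1) sets[[1]] else sets
}

normalize_drug <- function(name) {
  gsub("\\s+", " ", trimws(tolower(name)))
}

drug_class_sets <- function(norm, config) {
  lists <- list(
    antibiotic = normalize_drug(config$antibiotic_names),
    statin = normalize_drug(config$statin_names),
    norepinephrine = normalize_drug(config$norepinephrine_names),
    dopamine = normalize_drug(config$dopamine_names),
    dobutamine = normalize_drug(config$dobutamine_names)
  )
  purrr::map(norm, function(d) {
    cls <- names(lists)[vapply(lists, function(l) d %in% l, logical(1))]
    if (length(cls) == 0) "other" else cls
  })
}

# derived storage form: "+"-joined class set (lookup on unique names)
drug_class_column <- function(norm_drug, config) {
  u <- unique(norm_drug)
  uc <- vapply(drug_class_sets(u, config), paste, character(1), collapse = "+")
  uc[match(norm_drug, u)]
}

# helper: does a stored drug_class column contain a class?
has_drug_class <- function(drug_class, class) {
  vapply(strsplit(drug_class, "+", fixed = TRUE), function(s) class %in% s, logical(1))
}

#' Read an EHR bundle from delimited-text tables
#'
#' Reads the five CSV tables (UTF-8, header row), parses dates, derives
#' medication classes, canonicalizes lab units and validates the result.
#' An optional genotype dosage CSV (`patient_id` plus one column per SNP)
#' may be supplied.
#'
#' @param paths Named character vector with entries `patients`, `admissions`,
#'   `coded_events`, `medication_events`, `labs`, and optionally `genotypes`;
#'   or a directory containing files of those names with `.csv` extension.
#' @param config A [code_config][read_code_config].
#' @return A validated [ehr_bundle()].
#' @export
read_ehr_bundle <- function(paths, config = default_code_config()) {
  tabs <- c("patients", "admissions", "coded_events", "medication_events", "labs")
  if (length(paths) == 1 && is.null(names(paths)) && dir.exists(paths)) {
    paths <- setNames(file.path(paths, paste0(c(tabs, "genotypes"), ".csv")),
                      c(tabs, "genotypes"))
    if (!file.exists(paths[["genotypes"]])) paths <- paths[tabs]
  }
  miss <- setdiff(tabs, names(paths))
  if (length(miss) > 0) {
    abort(paste0("missing table path(s): ", paste(miss, collapse = ", ")),
          class = "sepsisldl_load_error")
  }
  read_one <- function(key, cols) {
    path <- paths[[key]]
    if (!file.exists(path)) {
      abort(sprintf("file for table '%s' not found: %s", key, path),
            class = "sepsisldl_load_error")
    }
    x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    miss <- setdiff(cols, names(x))
    if (length(miss) > 0) {
      abort(sprintf("file '%s' (table '%s') is missing column(s): %s",
                    path, key, paste(miss, collapse = ", ")),
            class = "sepsisldl_load_error")
    }
    x
  }
  patients <- read_one("patients", c("patient_id", "sex", "birth_date")) |>
    mutate(patient_id = as.character(.data$patient_id),
           birth_date = as.Date(.data$birth_date))
  admissions <- read_one("admissions",
                         c("patient_id", "admit_date", "discharge_date",
                           "icu_flag", "died_in_hospital")) |>
    mutate(patient_id = as.character(.data$patient_id),
           admit_date = as.Date(.data$admit_date),
           discharge_date = as.Date(.data$discharge_date),
           icu_flag = as.logical(.data$icu_flag),
           died_in_hospital = as.logical(.data$died_in_hospital))
  coded_events <- read_one("coded_events", c("patient_id", "date", "system", "code")) |>
    mutate(patient_id = as.character(.data$patient_id), date = as.Date(.data$date),
           code = as.character(.data$code))
  medication_events <- read_one("medication_events", c("patient_id", "date", "drug")) |>
    mutate(patient_id = as.character(.data$patient_id), date = as.Date(.data$date)) |>
    select(-any_of("drug_class"))
  labs <- read_one("labs", c("patient_id", "date", "analyte", "value", "inpatient")) |>
    mutate(patient_id = as.character(.data$patient_id), date = as.Date(.data$date),
           value = as.numeric(.data$value), inpatient = as.logical(.data$inpatient)) |>
    canonicalize_labs()
  genotypes <- NULL
  if ("genotypes" %in% names(paths) && !is.na(paths[["genotypes"]])) {
    genotypes <- readr::read_csv(paths[["genotypes"]], show_col_types = FALSE,
                                 progress = FALSE) |>
      mutate(patient_id = as.character(.data$patient_id))
  }
  ehr_bundle(patients, admissions, coded_events, medication_events, labs,
             genotypes = genotypes, config = config)
}

#' Write an EHR bundle as CSV tables
#'
#' Writes the five canonical tables (and genotypes, if present) to a
#' directory.  `read_ehr_bundle()` of the written directory reproduces the
#' bundle exactly (round-trip identity on canonicalized bundles).
#'
#' @param bundle An [ehr_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ehr_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in c("patients", "admissions", "coded_events", "medication_events", "labs")) {
    readr::write_csv(bundle[[tab]], file.path(dir, paste0(tab, ".csv")), progress = FALSE)
  }
  if (!is.null(bundle$genotypes)) {
    readr::write_csv(bundle$genotypes, file.path(dir, "genotypes.csv"), progress = FALSE)
  }
  invisible(dir)
}
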