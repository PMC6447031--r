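#' Map a diagnosis code to Charlson/Deyo categories
#'
#' Diagnosis codes are first grouped into PheCodes by longest-prefix match in
#' the configured `icd_to_phecode` map, then into modified Charlson/Deyo
#' comorbidity categories via `phecode_to_charlson`.  Unmapped codes yield an
#' empty set (not an error).
#'
#' @param code Diagnosis code string.
#' @param system Code system (`"ICD9CM"` or `"ICD10"`).
#' @param config A [code_config][read_code_config].
#' @return Character vector of category labels (possibly empty).
#' @examples
#' map_code_to_categories("428.0", "ICD9CM")    # congestive_heart_failure
#' map_code_to_categories("250.42", "ICD9CM")   # diabetes_complications
#' map_code_to_categories("V99.99", "ICD9CM")   # character(0)
#' @export
map_code_to_categories <- function(code, system, config = default_code_config()) {
  stopifnot(length(code) == 1, length(system) == 1)
  hits <- map_codes_to_categories(tibble(system = system, code = code), config)
  sort(unique(hits$category))
}

# vectorized: coded-event tibble (system, code, ...) -> rows with category
map_codes_to_categories <- function(events, config) {
  pmap <- config_phecode_map(config)
  cmap <- config_charlson_map(config)
  u <- events |> distinct(.data$system, .data$code)
  if (nrow(u) == 0) {
    return(events[0, ] |> mutate(category = character(0)))
  }
  hit <- u |>
    inner_join(pmap, by = "system", relationship = "many-to-many") |>
    filter(startsWith(.data$code, .data$prefix)) |>
    # longest prefix wins within a (system, code)
    arrange(.data$system, .data$code, -nchar(.data$prefix)) |>
    distinct(.data$system, .data$code, .keep_all = TRUE) |>
    inner_join(cmap, by = "phecode", relationship = "many-to-many") |>
    select("system", "code", "category")
  events |>
    inner_join(hit, by = c("system", "code"), relationship = "many-to-many")
}

#' Build per-episode comorbidity covariate vectors
#'
#' For each index episode, derives age at admission (completed years), sex,
#' and binary indicators for the configured Charlson/Deyo categories from
#' diagnosis codes dated in the year before the index admission (days -365
#' to -1 inclusive: codes on or after day 0 are outcome-era, not history).
#' The diabetes and diabetes-with-complications categories are merged into a
#' single `diabetes` indicator when the config requests it (the default).
#' Binary category indicators (never a summed index score) are the
#' adjustment covariates of the association models.
#'
#' @param bundle An [ehr_bundle()].
#' @param episodes Index episodes.
#' @param config A [code_config][read_code_config].
#' @return A tibble: `patient_id`, `age`, `sex`, then one `cm_<category>`
#'   logical column per (merged) category, in config order.
#' @export
build_covariates <- function(bundle, episodes, config = default_code_config()) {
  cats <- config$charlson_categories
  if (config$merge_diabetes) {
    cats <- setdiff(cats, "diabetes_complications")
  }
  lookback <- bundle$coded_events |>
    filter(.data$system %in% c("ICD9CM", "ICD10")) |>
    inner_join(episodes |> select("patient_id", "admit_date"), by = "patient_id",
               relationship = "many-to-many") |>
    mutate(rel = as.integer(.data$date - .data$admit_date)) |>
    filter(.data$rel >= -365L, .data$rel <= -1L)
  hits <- map_codes_to_categories(lookback, config)
  if (config$merge_diabetes && nrow(hits) > 0) {
    hits <- hits |>
      mutate(category = ifelse(.data$category == "diabetes_complications",
                               "diabetes", .data$category))
  }
  flags <- hits |>
    distinct(.data$patient_id, .data$category) |>
    mutate(value = TRUE) |>
    pivot_wider(names_from = "category", values_from = "value",
                values_fill = FALSE)
  for (cat in cats) if (!cat %in% names(flags)) flags[[cat]] <- FALSE
  base <- episodes |>
    select("patient_id", "admit_date") |>
    left_join(bundle$patients |> select("patient_id", "sex", "birth_date"),
              by = "patient_id") |>
    mutate(age = completed_years(.data$birth_date, .data$admit_date)) |>
    select("patient_id", "age", "sex")
  out <- base |> left_join(flags |> select("patient_id", all_of(cats)), by = "patient_id")
  out <- out |> mutate(across(all_of(cats), function(x) replace_na(x, FALSE)))
  names(out)[match(cats, names(out))] <- paste0("cm_", cats)
  out
}
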