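#' Code configuration for the EHR pipeline
#'
#' Every filter in the pipeline (infection definition, chronic-illness
#' exclusions, explicit sepsis codes, organ-dysfunction evidence codes,
#' antibiotic/statin/vasopressor name lists, and the diagnosis-code to
#' PheCode to Charlson/Deyo category maps) reads from a code configuration
#' object rather than from hard-coded constants.  The package ships a small,
#' deliberately illustrative default (`default_code_config()`); real analyses
#' are expected to substitute site-specific lists via [read_code_config()].
#'
#' A `code_config` is a named list with the entries documented in the shipped
#' YAML file (`system.file("extdata", "default_codes.yaml", package =
#' "sepsisldl")`).  Code-list matching is exact string equality; only the
#' `icd_to_phecode` map matches by longest code prefix.
#'
#' @param path Path to a YAML configuration file.
#' @return A `code_config` object (named list).
#' @examples
#' cfg <- default_code_config()
#' names(cfg)
#' @export
read_code_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("code config file not found: ", path), class = "sepsisldl_load_error")
  }
  raw <- yaml::read_yaml(path)
  new_code_config(raw)
}

#' @rdname read_code_config
#' @export
default_code_config <- function() {
  path <- system.file("extdata", "default_codes.yaml", package = "sepsisldl")
  read_code_config(path)
}

#' Write a code configuration to YAML
#'
#' @param config A `code_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_code_config <- function(config, path) {
  stopifnot(inherits(config, "code_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

new_code_config <- function(x) {
  required <- c(
    "infection_codes", "exclusion_condition_codes", "severe_sepsis_shock_codes",
    "ventilation_codes", "vasopressor_admin_codes", "icu_codes",
    "antibiotic_names", "statin_names", "norepinephrine_names",
    "dopamine_names", "dobutamine_names", "icd_to_phecode",
    "phecode_to_charlson", "charlson_categories", "significance_alpha"
  )
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("code config is missing entries: ", paste(missing, collapse = ", ")),
          class = "sepsisldl_config_error")
  }
  for (nm in required) {
    if (length(x[[nm]]) == 0) {
      abort(paste0("code config entry must be non-empty: ", nm),
            class = "sepsisldl_config_error")
    }
  }
  x$merge_diabetes <- isTRUE(x$merge_diabetes %||% TRUE)
  x$structural_absent_categories <- x$structural_absent_categories %||% character()
  structure(x, class = "code_config")
}

#' @export
print.code_config <- function(x, ...) {
  cat("<code_config>\n")
  counts <- vapply(unclass(x), function(e) {
    if (is.list(e)) length(unlist(e, use.names = FALSE)) else length(e)
  }, integer(1))
  for (nm in names(counts)) cat(sprintf("  %-32s %d entr%s\n", nm, counts[[nm]],
                                        if (counts[[nm]] == 1) "y" else "ies"))
  invisible(x)
}

# Flatten a system-keyed code list (e.g. infection_codes) into a tibble with
# columns system, code.
config_codes <- function(config, entry) {
  lst <- config[[entry]]
  if (is.null(lst)) abort(paste0("no config entry: ", entry), class = "sepsisldl_config_error")
  purrr::imap(lst, function(codes, sys) tibble(system = sys, code = as.character(codes))) |>
    list_rbind()
}

# icd_to_phecode map as a tibble (system, prefix, phecode)
config_phecode_map <- function(config) {
  purrr::map(config$icd_to_phecode, as_tibble) |> list_rbind()
}

# phecode_to_charlson map as a tibble (phecode, category)
config_charlson_map <- function(config) {
  purrr::map(config$phecode_to_charlson, as_tibble) |> list_rbind()
}

# category -> example diagnosis code, used by the synthetic generator
config_category_codes <- function(config) {
  purrr::imap(config$category_example_codes,
              function(e, cat) tibble(category = cat, system = e$system, code = e$code)) |>
    list_rbind()
}
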