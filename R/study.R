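#' Build the measured-LDL analysis table
#'
#' Runs the full measured-LDL arm of the pipeline and returns one analysis
#' row per index episode: exposure (`ldl_baseline` or, for the no-exclusions
#' variant, `ldl_closest`), outcomes from the sepsis phenotyper, and the
#' adjustment covariates.
#'
#' Variants:
#' \describe{
#'   \item{primary}{index = first infection episode occurring more than one
#'     year after an otherwise-qualifying LDL measurement; chronic-illness
#'     exclusions applied; exposure = median of qualifying LDL values.}
#'   \item{no_prior_infection}{the primary cohort, additionally dropping
#'     patients with any infection episode before their latest qualifying
#'     LDL measurement.}
#'   \item{closest_value_no_exclusions}{index = first infection episode; no
#'     LDL qualification and no chronic-illness exclusions; exposure = LDL
#'     value closest to admission.}
#' }
#'
#' @param bundle An [ehr_bundle()].
#' @param config A [code_config][read_code_config].
#' @param variant One of `"primary"`, `"no_prior_infection"`,
#'   `"closest_value_no_exclusions"`.
#' @return A tibble with attribute `attrition` (stage-by-stage patient
#'   counts).  The exposure column is named `ldl` in all variants.
#' @export
measured_analysis_table <- function(bundle, config = default_code_config(),
                                    variant = c("primary", "no_prior_infection",
                                                "closest_value_no_exclusions"),
                                    lipid_covariates = TRUE) {
  variant <- match.arg(variant)
  att <- list(patients = nrow(bundle$patients))
  eps <- find_infection_episodes(bundle, config)
  att$patients_with_infection_episode <- dplyr::n_distinct(eps$patient_id)

  if (variant == "closest_value_no_exclusions") {
    idx <- select_index_episodes(eps)
    ldl <- closest_ldl_all(bundle, idx)
    idx <- idx |> semi_join(ldl, by = "patient_id")
    att$with_any_ldl_value <- nrow(idx)
    expo <- ldl |> rename(ldl = "ldl_closest")
    if (lipid_covariates) {
      expo <- expo |> left_join(covariate_medians(bundle), by = "patient_id")
    }
  } else {
    # one index-independent qualifying scan serves both the anchor dates and
    # the baselines (only the >1-year separation depends on the index date)
    far_future <- smax(bundle$admissions$admit_date) + 100000L
    qual0 <- qualifying_ldl_all(
      bundle,
      bundle$labs |> filter(.data$analyte == "ldl") |>
        distinct(.data$patient_id) |> mutate(admit_date = far_future),
      config
    )
    anchors <- qual0 |>
      summarise(anchor_date = smin(date) + 365L, .by = "patient_id")
    idx <- select_index_episodes(eps, anchors)
    att$index_after_qualifying_ldl <- nrow(idx)
    idx <- apply_chronic_exclusions(idx, bundle, config)
    att$after_chronic_exclusions <- nrow(idx)
    base <- qual0 |>
      inner_join(idx |> select("patient_id", "admit_date"), by = "patient_id") |>
      filter(as.integer(.data$admit_date - .data$date) > 365L) |>
      summarise(ldl_baseline = median(value), n_qualifying = dplyr::n(),
                latest_qualifying_date = smax(date), .by = "patient_id")
    if (lipid_covariates) {
      base <- base |> left_join(covariate_medians(bundle), by = "patient_id")
    }
    idx <- idx |> semi_join(base, by = "patient_id")
    att$with_qualifying_baseline <- nrow(idx)
    if (variant == "no_prior_infection") {
      prior <- eps |>
        inner_join(base |> select("patient_id", "latest_qualifying_date"),
                   by = "patient_id") |>
        filter(.data$admit_date < .data$latest_qualifying_date) |>
        distinct(.data$patient_id)
      idx <- idx |> anti_join(prior, by = "patient_id")
      att$no_prior_infection <- nrow(idx)
    }
    expo <- base |> semi_join(idx, by = "patient_id") |>
      rename(ldl = "ldl_baseline")
  }
  pheno <- classify_sepsis(bundle, idx, config, evidence = FALSE)
  cov <- build_covariates(bundle, idx, config)
  out <- idx |>
    select("patient_id", "admit_date") |>
    inner_join(expo, by = "patient_id") |>
    inner_join(pheno |> select(-"admit_date"), by = "patient_id") |>
    inner_join(cov, by = "patient_id")
  att$analysis_rows <- nrow(out)
  attr(out, "attrition") <- attrition_tibble(att)
  out
}

# all-record medians of HDL / triglycerides / BMI plus EHR length, for the
# extended adjustment set
covariate_medians <- function(bundle) {
  med <- bundle$labs |>
    filter(.data$analyte %in% c("hdl", "triglycerides", "bmi")) |>
    summarise(hdl_median = median(value[analyte == "hdl"]),
              tg_median = median(value[analyte == "triglycerides"]),
              bmi_median = median(value[analyte == "bmi"]),
              .by = "patient_id")
  med |> full_join(ehr_length_years(bundle), by = "patient_id")
}

#' Build the genetic-score analysis table
#'
#' Index = each genotyped patient's first infection episode; exposure = the
#' weighted-allele genetic score; covariates = age and sex only (genetic
#' scores are fixed at conception, so illness-era comorbidities are not
#' confounders of the score).
#'
#' @inheritParams measured_analysis_table
#' @param weights SNP-weight table (default: the shipped synthetic panel).
#' @return A tibble with attribute `attrition`.
#' @export
grs_analysis_table <- function(bundle, config = default_code_config(),
                               weights = default_snp_weights()) {
  att <- list(patients = nrow(bundle$patients))
  if (is.null(bundle$genotypes)) {
    abort("bundle has no genotypes: cannot build the genetic-score cohort",
          class = "sepsisldl_param_error")
  }
  eps <- find_infection_episodes(bundle, config)
  att$patients_with_infection_episode <- dplyr::n_distinct(eps$patient_id)
  idx <- select_index_episodes(eps)
  scores <- compute_grs(bundle$genotypes, weights)
  idx <- idx |> semi_join(scores, by = "patient_id")
  att$genotyped <- nrow(idx)
  pheno <- classify_sepsis(bundle, idx, config, evidence = FALSE)
  cov <- build_covariates(bundle, idx, config)
  out <- idx |>
    select("patient_id", "admit_date") |>
    inner_join(scores, by = "patient_id") |>
    inner_join(pheno |> select(-"admit_date"), by = "patient_id") |>
    inner_join(cov |> select("patient_id", "age", "sex"), by = "patient_id")
  att$analysis_rows <- nrow(out)
  attr(out, "attrition") <- attrition_tibble(att)
  out
}

attrition_tibble <- function(att) {
  tibble(stage = names(att), n = unlist(att, use.names = FALSE))
}

study_outcomes <- c("sepsis", "icu_admission", "in_hospital_death")

#' Run the full association study
#'
#' Executes the complete model grid on a bundle: for each outcome (sepsis,
#' ICU admission, in-hospital death), unadjusted and adjusted (age, sex and
#' comorbidity-category indicators) models of measured baseline LDL per 1 SD,
#' the corresponding genetic-score models (adjusted for age and sex only),
#' optional quartile models (highest quartile as reference), the extended
#' adjustment (adds median HDL, triglycerides, BMI and EHR length), and
#' optional sensitivity cohort variants.
#'
#' @param bundle An [ehr_bundle()].
#' @param config A [code_config][read_code_config].
#' @param weights SNP-weight table for the genetic score; set `NULL` to skip
#'   the genetic arm.
#' @param variants Cohort variants to run (see [measured_analysis_table()]).
#' @param include_quartiles Also fit quartile models.
#' @param include_extended Also fit the extended adjustment sensitivity
#'   models.
#' @return A `sepsis_study` tibble: one row per fitted term, with columns
#'   `cohort`, `outcome`, `predictor`, `form`, `adjustment`, `term`, `n`,
#'   `n_events`, `log_or`, `se`, `or`, `ci_low`, `ci_high`, `p_value`,
#'   `significant`.  Attributes: `attrition` (named list of stage-count
#'   tibbles) and `tables` (the analysis tables).
#' @export
run_study <- function(bundle, config = default_code_config(),
                      weights = default_snp_weights(),
                      variants = "primary",
                      include_quartiles = TRUE,
                      include_extended = FALSE) {
  alpha <- config$significance_alpha %||% 0.0167
  rows <- list()
  attrition <- list()
  tables <- list()

  fit_grid <- function(tab, cohort, predictor, adj_sets, forms) {
    cm_cols <- grep("^cm_", names(tab), value = TRUE)
    sets <- list(
      unadjusted = character(0),
      adjusted = c("age", "sex", cm_cols),
      age_sex = c("age", "sex"),
      extended = c("age", "sex", cm_cols, "hdl_median", "tg_median",
                   "bmi_median", "ehr_length_years")
    )
    for (outc in study_outcomes) {
      if (nrow(tab) == 0 || length(unique(tab[[outc]])) < 2) next
      for (adj in adj_sets) {
        for (form in forms) {
          fitter <- if (form == "per_sd") fit_per_sd else fit_quartiles
          res <- withCallingHandlers(
            tryCatch(
              suppressMessages(fitter(tab, outc, predictor,
                                      adjust = sets[[adj]], alpha = alpha,
                                      label = adj)),
              sepsisldl_fit_error = function(e) NULL,
              sepsisldl_quartile_error = function(e) NULL
            ),
            sepsisldl_low_events_warning = function(w) {
              invokeRestart("muffleWarning")
            }
          )
          if (!is.null(res)) {
            rows[[length(rows) + 1L]] <<- as_tibble(res) |>
              mutate(cohort = cohort, .before = 1)
          }
        }
      }
    }
  }

  for (v in variants) {
    tab <- measured_analysis_table(bundle, config, variant = v)
    cohort <- paste0("measured_", v)
    tables[[cohort]] <- tab
    attrition[[cohort]] <- attr(tab, "attrition")
    adj <- c("unadjusted", "adjusted")
    if (include_extended || v == "closest_value_no_exclusions") {
      adj <- c(adj, "extended")
    }
    forms <- if (include_quartiles) c("per_sd", "quartiles") else "per_sd"
    fit_grid(tab, cohort, "ldl", adj, forms)
  }
  if (!is.null(weights) && !is.null(bundle$genotypes)) {
    gtab <- grs_analysis_table(bundle, config, weights)
    tables$grs <- gtab
    attrition$grs <- attr(gtab, "attrition")
    forms <- if (include_quartiles) c("per_sd", "quartiles") else "per_sd"
    fit_grid(gtab, "grs", "grs", c("unadjusted", "age_sex"), forms)
  }
  out <- if (length(rows) > 0) list_rbind(rows) else empty_study_rows()
  structure(out, class = c("sepsis_study", class(out)),
            attrition = attrition, tables = tables, alpha = alpha)
}

empty_study_rows <- function() {
  tibble(cohort = character(0), outcome = character(0), predictor = character(0),
         form = character(0), adjustment = character(0), term = character(0),
         n = integer(0), n_events = integer(0), log_or = numeric(0),
         se = numeric(0), or = numeric(0), ci_low = numeric(0),
         ci_high = numeric(0), p_value = numeric(0), significant = logical(0))
}

#' @export
print.sepsis_study <- function(x, ...) {
  cat(sprintf("<sepsis_study> %d fitted terms\n", nrow(x)))
  NextMethod()
}

#' Attrition table of a study
#'
#' Stage-by-stage patient counts for each analysis cohort of a
#' [run_study()] result (a Figure-1-style accounting of how each analysis
#' population was derived).
#'
#' @param study A `sepsis_study`.
#' @return A tibble: `cohort`, `stage`, `n`.
#' @export
study_attrition <- function(study) {
  att <- attr(study, "attrition")
  purrr::imap(att, function(tb, cohort) tb |> mutate(cohort = cohort, .before = 1)) |>
    list_rbind()
}

#' Run the whole pipeline from simulation parameters
#'
#' One-call orchestration: simulate a bundle (or accept one), run the full
#' study, and optionally write every stage artifact (the five bundle CSVs,
#' episode, baseline, phenotype, covariate and score tables, the results
#' table and the attrition log) to a directory.  A single seed inside
#' `params` governs all randomness, so a run is reproducible from its
#' parameters alone.
#'
#' @param params A [sim_params()]; ignored if `bundle` is supplied.
#' @param bundle Optionally, an existing [ehr_bundle()].
#' @param config A [code_config][read_code_config].
#' @param out_dir Optional output directory for stage artifacts.
#' @param ... Passed to [run_study()].
#' @return A list: `study` (the results), `bundle`, and `truth` (when
#'   simulated).
#' @export
run_pipeline <- function(params = sim_params(), bundle = NULL,
                         config = default_code_config(), out_dir = NULL, ...) {
  truth <- NULL
  if (is.null(bundle)) {
    sim <- generate_ehr_bundle(params, config)
    bundle <- sim$bundle
    truth <- sim$truth
  }
  study <- run_study(bundle, config, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ehr_bundle(bundle, out_dir)
    eps <- find_infection_episodes(bundle, config)
    readr::write_csv(eps, file.path(out_dir, "episodes.csv"), progress = FALSE)
    tables <- attr(study, "tables")
    for (nm in names(tables)) {
      readr::write_csv(tables[[nm]], file.path(out_dir, paste0("analysis_", nm, ".csv")),
                       progress = FALSE)
    }
    readr::write_csv(as_tibble(study), file.path(out_dir, "results.csv"),
                     progress = FALSE)
    readr::write_csv(study_attrition(study), file.path(out_dir, "attrition.csv"),
                     progress = FALSE)
    if (!is.null(truth)) {
      readr::write_csv(truth, file.path(out_dir, "truth.csv"), progress = FALSE)
    }
  }
  list(study = study, bundle = bundle, truth = truth)
}
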