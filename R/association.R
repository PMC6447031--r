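#' Logistic association of an exposure with a sepsis outcome, per 1 SD
#'
#' Fits `outcome ~ z(predictor) + covariates` by logistic maximum likelihood,
#' where `z()` standardizes the predictor by the mean and SD of the analysis
#' cohort (after row-wise deletion of missing values), so that the reported
#' odds ratio is per 1-SD increase.  Confidence intervals and p-values are
#' Wald-based; significance is judged against a two-sided threshold `alpha`
#' (default 0.0167, the Bonferroni-style constant for three outcomes).
#' Constant covariate columns (e.g. comorbidity categories structurally
#' absent from the cohort) are dropped with a notice.
#'
#' @param data Analysis tibble, one row per index episode.
#' @param outcome Name of a logical/0-1 outcome column (`sepsis`,
#'   `icu_admission` or `in_hospital_death`).
#' @param predictor Name of a numeric exposure column (e.g. `ldl_baseline`
#'   or `grs`).
#' @param adjust Character vector of covariate column names (empty for the
#'   unadjusted model).
#' @param alpha Two-sided significance threshold.
#' @param label Optional adjustment-set label stored in the result (defaults
#'   to `"unadjusted"` or `"adjusted"`).
#' @param min_events Fewer outcome events than this flags the fit (it is
#'   still returned).
#' @return An object of class `sepsis_assoc`; see [tidy()] / [glance()]
#'   methods and `as_tibble()` for the one-row (or per-quartile) summary.
#' @examples
#' d <- tibble::tibble(y = rbinom(500, 1, 0.3), x = rnorm(500))
#' fit_per_sd(d, "y", "x")
#' @export
fit_per_sd <- function(data, outcome, predictor, adjust = character(),
                       alpha = 0.0167, label = NULL, min_events = 10) {
  prep <- prepare_model_data(data, outcome, predictor, adjust)
  df <- prep$df
  sd_x <- sd(df$.x)
  if (!is.finite(sd_x) || sd_x == 0) {
    abort(paste0("predictor has zero variance: ", predictor),
          class = "sepsisldl_fit_error")
  }
  df$.z <- (df$.x - mean(df$.x)) / sd_x
  fit <- safe_logistic(stats::reformulate(c(".z", prep$adjust), response = ".y"),
                       df, offending = predictor)
  est <- summary(fit)$coefficients[".z", ]
  res <- assoc_row(est, term = "per_sd", alpha = alpha)
  new_sepsis_assoc(fit, res, outcome, predictor, "per_sd",
                   label %||% (if (length(adjust) == 0) "unadjusted" else "adjusted"),
                   prep, alpha, sd_x = sd_x, min_events = min_events)
}

#' Quartile association models (highest quartile as reference)
#'
#' Cuts the predictor at its empirical 25th/50th/75th percentiles (linear
#' interpolation; boundary ties assigned to the lower quartile), codes
#' quartile membership as indicators with the highest quartile (Q4) as the
#' reference, and fits the same logistic model as [fit_per_sd()].  Returns
#' odds ratios for Q1, Q2 and Q3 versus Q4.
#'
#' @inheritParams fit_per_sd
#' @return A `sepsis_assoc` whose summary has one row per non-reference
#'   quartile.
#' @export
fit_quartiles <- function(data, outcome, predictor, adjust = character(),
                          alpha = 0.0167, label = NULL, min_events = 10) {
  prep <- prepare_model_data(data, outcome, predictor, adjust)
  df <- prep$df
  if (length(unique(df$.x)) < 4) {
    abort(paste0("fewer than 4 distinct predictor values: ", predictor),
          class = "sepsisldl_quartile_error")
  }
  cuts <- quantile(df$.x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  q <- 1L + (df$.x > cuts[1]) + (df$.x > cuts[2]) + (df$.x > cuts[3])
  if (length(unique(q)) < 4) {
    abort("ties leave an empty quartile", class = "sepsisldl_quartile_error")
  }
  df$.q <- factor(paste0("Q", q), levels = c("Q4", "Q1", "Q2", "Q3"))
  fit <- safe_logistic(stats::reformulate(c(".q", prep$adjust), response = ".y"),
                       df, offending = predictor)
  cf <- summary(fit)$coefficients
  res <- purrr::map(paste0("Q", 1:3), function(qq) {
    assoc_row(cf[paste0(".q", qq), ], term = qq, alpha = alpha)
  }) |> list_rbind()
  new_sepsis_assoc(fit, res, outcome, predictor, "quartiles",
                   label %||% (if (length(adjust) == 0) "unadjusted" else "adjusted"),
                   prep, alpha, cuts = cuts, min_events = min_events)
}

prepare_model_data <- function(data, outcome, predictor, adjust) {
  stopifnot(outcome %in% names(data), predictor %in% names(data))
  miss <- setdiff(adjust, names(data))
  if (length(miss) > 0) {
    abort(paste0("missing covariate column(s): ", paste(miss, collapse = ", ")),
          class = "sepsisldl_fit_error")
  }
  df <- data |>
    transmute(.y = as.integer(.data[[outcome]]),
              .x = as.numeric(.data[[predictor]]),
              across(all_of(adjust)))
  if (!all(df$.y %in% c(0L, 1L, NA))) {
    abort(paste0("outcome must be binary: ", outcome), class = "sepsisldl_fit_error")
  }
  df <- df[complete.cases(df), , drop = FALSE]
  # sex and logical flags as numeric-friendly factors; drop constant columns
  dropped <- character(0)
  for (col in adjust) {
    if (is.character(df[[col]])) df[[col]] <- factor(df[[col]])
    if (length(unique(df[[col]])) < 2) {
      dropped <- c(dropped, col)
    }
  }
  if (length(dropped) > 0) {
    inform(paste0("dropping constant covariate(s): ", paste(dropped, collapse = ", ")))
  }
  list(df = df, adjust = setdiff(adjust, dropped), dropped = dropped)
}

safe_logistic <- function(formula, df, offending) {
  fit <- withCallingHandlers(
    glm(formula, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        abort(paste0("separation detected while fitting predictor: ", offending),
              class = "sepsisldl_fit_error")
      }
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged || anyNA(coef(fit))) {
    abort(paste0("logistic fit failed to converge for predictor: ", offending),
          class = "sepsisldl_fit_error")
  }
  fit
}

assoc_row <- function(est, term, alpha) {
  b <- est[["Estimate"]]; se <- est[["Std. Error"]]
  zcrit <- qnorm(0.975)
  p <- 2 * stats::pnorm(-abs(b / se))
  tibble(term = term, log_or = b, se = se, or = exp(b),
         ci_low = exp(b - zcrit * se), ci_high = exp(b + zcrit * se),
         p_value = p, significant = p < alpha)
}

new_sepsis_assoc <- function(fit, res, outcome, predictor, form, adjustment,
                             prep, alpha, sd_x = NA_real_, cuts = NULL,
                             min_events = 10) {
  n <- nrow(prep$df)
  n_events <- sum(prep$df$.y)
  if (n_events < min_events) {
    warn(sprintf("only %d events for outcome '%s': estimates unstable",
                 n_events, outcome),
         class = "sepsisldl_low_events_warning")
  }
  structure(
    list(fit = fit,
         result = res |> mutate(outcome = outcome, predictor = predictor,
                                form = form, adjustment = adjustment,
                                n = n, n_events = n_events, .before = 1),
         outcome = outcome, predictor = predictor, form = form,
         adjustment = adjustment, adjust_used = prep$adjust,
         dropped_covariates = prep$dropped, sd_x = sd_x, cuts = cuts,
         alpha = alpha, low_events = n_events < min_events),
    class = "sepsis_assoc"
  )
}

#' @export
print.sepsis_assoc <- function(x, ...) {
  cat(sprintf("<sepsis_assoc> %s ~ %s (%s, %s)\n", x$outcome, x$predictor,
              x$form, x$adjustment))
  print(as_tibble(x))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.sepsis_assoc <- function(x, ...) x$result

#' Tidy a fitted sepsis association model
#'
#' `tidy()` returns the coefficient table of the underlying logistic fit
#' (odds-ratio scale when `exponentiate = TRUE`, the default for the summary
#' row); `glance()` returns one row of model-level statistics.
#'
#' @param x A `sepsis_assoc` object.
#' @param exponentiate Report odds ratios rather than log-odds.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.sepsis_assoc <- function(x, exponentiate = TRUE, ...) {
  cf <- summary(x$fit)$coefficients
  out <- tibble(term = rownames(cf), estimate = cf[, "Estimate"],
                std.error = cf[, "Std. Error"], statistic = cf[, "z value"],
                p.value = cf[, "Pr(>|z|)"])
  if (exponentiate) {
    zc <- qnorm(0.975)
    out <- out |>
      mutate(conf.low = exp(.data$estimate - zc * .data$std.error),
             conf.high = exp(.data$estimate + zc * .data$std.error),
             estimate = exp(.data$estimate))
  }
  out
}

#' @rdname tidy.sepsis_assoc
#' @exportS3Method generics::glance
glance.sepsis_assoc <- function(x, ...) {
  f <- x$fit
  tibble(n = x$result$n[1], n_events = x$result$n_events[1],
         null.deviance = f$null.deviance, deviance = f$deviance,
         AIC = stats::AIC(f), converged = f$converged,
         dropped_covariates = length(x$dropped_covariates),
         low_events = x$low_events)
}
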