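#' Forest plot of a study's odds ratios
#'
#' One panel per cohort, points at the odds-ratio estimates with 95% Wald
#' intervals, on a log scale, with the null (OR = 1) marked.
#'
#' @param object A `sepsis_study` from [run_study()].
#' @param form Which model form to plot (`"per_sd"` or `"quartiles"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sepsis_study <- function(object, form = "per_sd", ...) {
  df <- as_tibble(object) |>
    filter(.data$form == !!form) |>
    mutate(label = paste(.data$outcome, .data$term, sep = " "),
           adjustment = factor(.data$adjustment,
                               levels = c("unadjusted", "age_sex", "adjusted",
                                          "extended")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$label,
                                   colour = .data$adjustment)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~cohort, scales = "free_y") +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL, colour = "Model") +
    ggplot2::theme_minimal()
}

#' Attrition (cohort-derivation) plot
#'
#' Bar chart of patient counts remaining after each sequential filter, per
#' analysis cohort.
#'
#' @param study A `sepsis_study`.
#' @return A ggplot object.
#' @export
plot_attrition <- function(study) {
  df <- study_attrition(study) |>
    mutate(stage = factor(.data$stage, levels = rev(unique(.data$stage))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), hjust = -0.1, size = 3) +
    ggplot2::facet_wrap(~cohort) +
    ggplot2::labs(x = "Patients", y = NULL) +
    ggplot2::theme_minimal()
}
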