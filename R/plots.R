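#' Distribution of predicted differential treatment effects
#'
#' Histogram of (updated) predicted SGLT2i - DPP4i differences, optionally
#' faceted by ethnicity group. Negative values are a predicted HbA1c
#' benefit on SGLT2i.
#'
#' @param data Data frame with a `pred_diff` column (e.g. the `cohort`
#'   element of a [run_validation()] report) and, if faceting, `group`.
#' @param by_group Facet by ethnicity group?
#' @return A ggplot object.
#' @export
plot_benefit_distribution <- function(data, by_group = TRUE) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$pred_diff)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Predicted HbA1c difference, SGLT2i - DPP4i (mmol/mol)",
                  y = "Initiations") +
    ggplot2::theme_minimal()
  if (by_group && !is.null(data$group)) {
    p <- p + ggplot2::facet_wrap(~group, scales = "free_y")
  }
  p
}

#' Decile calibration plot
#'
#' Mean predicted difference versus covariate-adjusted observed arm
#' difference per decile, with 95% confidence bars; the red identity line
#' is perfect calibration.
#'
#' @param calibration A [calibration_table()] result (optionally with an
#'   `ethnicity` column for faceting).
#' @return A ggplot object.
#' @export
plot_calibration <- function(calibration) {
  p <- ggplot2::ggplot(calibration,
                       ggplot2::aes(x = .data$mean_pred_diff, y = .data$adj_obs_diff)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.15, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Mean predicted HbA1c difference (mmol/mol)",
                  y = "Adjusted observed HbA1c difference (mmol/mol)") +
    ggplot2::theme_minimal()
  if (!is.null(calibration$ethnicity)) p <- p + ggplot2::facet_wrap(~ethnicity)
  p
}

#' Subgroup outcome plot
#'
#' Bar chart of one unadjusted outcome (glycaemic response, weight change
#' or discontinuation proportion) by benefit subgroup and drug class, with
#' 95% confidence bars; faceted by ethnicity when present.
#'
#' @param subgroups A [subgroup_summary()] result.
#' @param outcome One of `"response"`, `"weight"`, `"discontinuation"`.
#' @return A ggplot object.
#' @export
plot_subgroups <- function(subgroups,
                           outcome = c("response", "weight", "discontinuation")) {
  outcome <- match.arg(outcome)
  cols <- switch(outcome,
    response = c("mean_response", "response_ci_low", "response_ci_high",
                 "HbA1c response (mmol/mol)"),
    weight = c("mean_weight_change", "weight_ci_low", "weight_ci_high",
               "Weight change (kg)"),
    discontinuation = c("discontinuation", "disc_ci_low", "disc_ci_high",
                        "Discontinuation proportion"))
  df <- subgroups
  df$subgroup <- factor(df$subgroup, levels = subgroup_levels())
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$subgroup, y = .data[[cols[1]]],
                                        fill = .data$drug)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[cols[2]]], ymax = .data[[cols[3]]]),
                           position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::labs(x = "Predicted benefit subgroup", y = cols[4], fill = "Drug") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  if (!is.null(df$ethnicity)) p <- p + ggplot2::facet_wrap(~ethnicity)
  p
}

#' @export
autoplot.validation_report <- function(object, ...) {
  plot_calibration(object$calibration)
}
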