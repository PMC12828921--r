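#' Reliability diagram
#'
#' Observed event rate against mean predicted probability per equal-count
#' bin, with the identity line of perfect calibration.
#'
#' @param reliability A [reliability_table()].
#' @return A ggplot.
#' @export
plot_reliability <- function(reliability) {
  ggplot2::ggplot(reliability,
                  ggplot2::aes(x = .data$p_mean, y = .data$event_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), colour = "#2166ac") +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted probability",
                  y = "Observed event rate",
                  title = "Reliability diagram") +
    ggplot2::theme_minimal()
}

#' Decision-curve plot
#'
#' @param dc A [decision_curve()] table.
#' @return A ggplot.
#' @export
plot_decision_curve <- function(dc) {
  long <- tidyr::pivot_longer(dc, c("nb_model", "nb_all", "nb_none"),
                              names_to = "strategy", values_to = "net_benefit")
  long$strategy <- factor(long$strategy, c("nb_model", "nb_all", "nb_none"),
                          c("Model", "Treat all", "Treat none"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold,
                                     y = .data$net_benefit,
                                     colour = .data$strategy,
                                     linetype = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.05, NA)) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                  colour = NULL, linetype = NULL,
                  title = "Decision-curve analysis") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of pooled dose predictions
#'
#' @param pred,true Aligned dose vectors (mm).
#' @return A ggplot.
#' @export
plot_bland_altman <- function(pred, true) {
  ba <- bland_altman(pred, true)
  df <- tibble(mean = (pred + true) / 2, diff = pred - true)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "red",
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        colour = "grey40", linetype = "dashed") +
    ggplot2::labs(x = "Mean of predicted and reference dose (mm)",
                  y = "Predicted - reference (mm)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Histogram of simulated recession/resection doses
#'
#' Recessions are shown as negative values and resections positive,
#' mirroring the usual presentation of surgical-dose distributions.
#'
#' @param cohort A cohort tibble.
#' @return A ggplot.
#' @export
plot_dose_histogram <- function(cohort) {
  long <- tidyr::pivot_longer(cohort[c("patient_id", dose_cols())],
                              -"patient_id", names_to = "slot",
                              values_to = "dose") %>%
    filter(.data$dose > 0) %>%
    mutate(procedure = ifelse(grepl("recess", .data$slot), "recession",
                              "resection"),
           signed = ifelse(.data$procedure == "recession", -.data$dose,
                           .data$dose))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$signed,
                                     fill = .data$procedure)) +
    ggplot2::geom_histogram(binwidth = 0.5, boundary = 0, colour = "white",
                            linewidth = 0.2) +
    ggplot2::labs(x = "Dose (mm; recessions negative, resections positive)",
                  y = "Muscle count", fill = NULL,
                  title = "Simulated dose distribution") +
    ggplot2::theme_minimal()
}

#' Permutation-importance bar chart
#'
#' @param importance A [permutation_importance()] table.
#' @return A ggplot.
#' @export
plot_importance <- function(importance) {
  imp <- mutate(importance,
                feature = factor(.data$feature,
                                 levels = rev(importance$feature)))
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance_mean,
                                    y = .data$feature)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_errorbar(ggplot2::aes(
      xmin = .data$importance_mean - .data$importance_sd,
      xmax = .data$importance_mean + .data$importance_sd), width = 0.3) +
    ggplot2::labs(x = "Metric degradation when permuted", y = NULL,
                  title = "Permutation feature importance") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.strabnet_report <- function(object,
                                     type = c("reliability",
                                              "decision_curve"), ...) {
  type <- match.arg(type)
  switch(type,
         reliability = plot_reliability(object$calibration$reliability),
         decision_curve = plot_decision_curve(object$decision_curve))
}
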