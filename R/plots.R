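#' Plot a sensorgram series
#'
#' Response-vs-time traces, one line per injection cycle, colored by analyte
#' concentration.
#'
#' @param data Sensorgram tibble.
#' @return A ggplot object.
#' @export
plot_sensorgrams <- function(data) {
  validate_sensorgram(data)
  ggplot2::ggplot(data, ggplot2::aes(.data$time_s, .data$response_ru,
                                     group = .data$cycle_id,
                                     color = factor(.data$conc_M * 1e6))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Response (RU)",
                  color = "Analyte (µM)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(.data$time_s, group = .data$cycle_id)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed_ru),
                       color = "grey55") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_ru),
                       linetype = "dashed") +
    ggplot2::labs(x = "Time (s)", y = "Response (RU)",
                  title = sprintf("%s model, %s fit (chi-square %.3g)",
                                  object$model, object$scope, object$chisq)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.isotherm_fit <- function(object, ...) {
  curve <- tibble::tibble(
    conc_M = exp(seq(log(min(object$data$conc_M)),
                     log(max(object$data$conc_M)), length.out = 200)))
  curve$response_ru <- object$B_max * curve$conc_M /
    (object$K_D + curve$conc_M)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$conc_M * 1e6, .data$response_ru)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve) +
    ggplot2::labs(x = "Analyte (µM)", y = "Steady-state response (RU)",
                  title = sprintf("One-site fit: K_D = %.3g µM",
                                  object$K_D * 1e6)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ic50_fit <- function(object, ...) {
  d <- object$data[object$data$inhibitor_nM > 0, ]
  curve <- tibble::tibble(
    inhibitor_nM = exp(seq(log(min(d$inhibitor_nM)),
                           log(max(d$inhibitor_nM)), length.out = 200)))
  curve$signal <- object$bottom + (object$top - object$bottom) /
    (1 + (curve$inhibitor_nM / object$ic50_nM)^object$hill)
  ggplot2::ggplot(d, ggplot2::aes(.data$inhibitor_nM, .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Inhibitor (nM)", y = "Signal (counts)",
                  title = sprintf("4PL fit: IC50 = %.3g nM", object$ic50_nM)) +
    ggplot2::theme_minimal()
}
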