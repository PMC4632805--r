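#' Plot a trolox calibration line
#'
#' Scatter of response against trolox concentration with the fitted OLS line.
#'
#' @param object An `aox_calibration` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.aox_calibration <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$concentration, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept,
      colour = "steelblue"
    ) +
    ggplot2::labs(
      x = "Trolox concentration (µM)", y = "Response",
      title = sprintf("Trolox calibration (R² = %.4f)", object$r_squared)
    )
}

#' @rdname autoplot.aox_calibration
#' @exportS3Method ggplot2::autoplot
autoplot.aox_assay <- function(object, ...) {
  autoplot(object$calibration) +
    ggplot2::labs(title = sprintf(
      "%s trolox calibration (R² = %.4f)", object$assay, object$calibration$r_squared
    ))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot kinetic curves of a plate
#'
#' One line per well, coloured by role, for visual QC of decay kinetics.
#'
#' @param plate A long-format plate tibble.
#' @return A ggplot object.
#' @export
plot_kinetics <- function(plate) {
  plate <- validate_plate(plate)
  ggplot2::ggplot(
    plate,
    ggplot2::aes(x = .data$time, y = .data$signal, group = .data$well, colour = .data$role)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "Signal")
}

#' Plot a descriptor screen summary
#'
#' Bar chart of Pearson r per descriptor, significant correlations filled.
#'
#' @param results Output of [screen_descriptors()].
#' @return A ggplot object.
#' @export
plot_screen <- function(results) {
  ggplot2::ggplot(
    results,
    ggplot2::aes(x = .data$descriptor, y = .data$r, fill = .data$significant)
  ) +
    ggplot2::geom_col() +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = NULL, y = "Pearson r")
}

#' Plot ranked integral scores
#'
#' Bar chart of the integral score for a ranked peptide table.
#'
#' @param ranked Output of [rank_peptides()].
#' @param top Show at most this many peptides.
#' @return A ggplot object.
#' @export
plot_scores <- function(ranked, top = 20) {
  ranked <- utils::head(ranked, top)
  ranked$sequence <- factor(ranked$sequence, levels = rev(ranked$sequence))
  ggplot2::ggplot(ranked, ggplot2::aes(x = .data$score, y = .data$sequence)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Integral score I", y = NULL)
}
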