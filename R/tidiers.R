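#' Tidiers for calibration and assay objects
#'
#' [tidy()] on an `aox_calibration` returns the coefficient table; [glance()]
#' a one-row model summary. On an `aox_assay`, [tidy()] returns the
#' per-sample AOC table and [glance()] the calibration summary plus well
#' counts.
#'
#' @param x An `aox_calibration` or `aox_assay` object.
#' @param ... Unused.
#' @return A tibble.
#' @name aoxpep-tidiers
NULL

#' @rdname aoxpep-tidiers
#' @exportS3Method generics::tidy
tidy.aox_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname aoxpep-tidiers
#' @exportS3Method generics::glance
glance.aox_calibration <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept,
    r_squared = x$r_squared, n_points = as.integer(x$n_points)
  )
}

#' @rdname aoxpep-tidiers
#' @exportS3Method generics::tidy
tidy.aox_assay <- function(x, ...) {
  x$samples
}

#' @rdname aoxpep-tidiers
#' @exportS3Method generics::glance
glance.aox_assay <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(assay = x$assay, n_wells = nrow(x$wells)),
    glance(x$calibration)
  )
}
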