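#' Area under a kinetic curve
#'
#' Trapezoidal integral of a plate-reader kinetic curve over time (minutes).
#' With `normalize = TRUE` (the convention for ORAC fluorescein decay) the
#' signal is divided by its first reading, so the area has units of minutes
#' and a fully protected fluorophore over a window of length T gives T.
#'
#' @param time Time points in minutes, strictly increasing.
#' @param signal Non-negative signal values (fluorescence or OD), same length.
#' @param normalize Divide by the initial reading before integrating.
#' @return The integral (minutes when normalized).
#' @examples
#' curve_auc(0:10, rep(2, 11))           # 10
#' curve_auc(0:10, seq(1, 0, length = 11)) # 5
#' @export
curve_auc <- function(time, signal, normalize = TRUE) {
  check_curve(time, signal)
  if (normalize) {
    if (signal[1] <= 0) abort("cannot normalize: initial signal is not positive")
    signal <- signal / signal[1]
  }
  pracma::trapz(time, signal)
}

check_curve <- function(time, signal) {
  if (length(time) != length(signal)) abort("time and signal lengths differ")
  if (length(time) < 2) abort("a kinetic curve needs at least 2 points")
  if (any(!is.finite(time)) || any(!is.finite(signal))) abort("non-finite curve values")
  if (any(diff(time) <= 0)) abort("time points must be strictly increasing")
  if (any(signal < 0)) abort("signal values must be non-negative")
  invisible(NULL)
}

#' Net area under the curve
#'
#' The ORAC response: area under the (normalized) sample decay curve minus the
#' area under the blank (no antioxidant) decay curve.
#'
#' @param sample,blank Data frames with columns `time` (minutes) and `signal`.
#' @param normalize Normalize both curves to their initial reading.
#' @return Net AUC in minutes.
#' @export
net_auc <- function(sample, blank, normalize = TRUE) {
  curve_auc(sample$time, sample$signal, normalize) -
    curve_auc(blank$time, blank$signal, normalize)
}

#' TEAC response: absorbance decline at the read time
#'
#' The ABTS decolorization response of a sample is the OD at `t_read`
#' (default 40.5 min, the end of the registration window) of the control
#' (radical + solvent) minus that of the sample, with linear interpolation
#' between measured time points.
#'
#' @param sample,control Data frames with columns `time` (minutes) and
#'   `signal` (OD at 734 nm).
#' @param t_read Read time in minutes; must lie within both curves.
#' @return The OD decline (dimensionless).
#' @export
teac_response <- function(sample, control, t_read = 40.5) {
  interp_at(control$time, control$signal, t_read) -
    interp_at(sample$time, sample$signal, t_read)
}

interp_at <- function(time, signal, t) {
  check_curve(time, signal)
  if (t < min(time) || t > max(time)) {
    abort(sprintf("read time %.3g min is outside the curve range [%.3g, %.3g]", t, min(time), max(time)))
  }
  stats::approx(time, signal, xout = t)$y
}

#' Fit a trolox calibration line
#'
#' Ordinary least-squares regression of assay response (OD decline or net
#' AUC) on trolox concentration, the quantitation backbone of both assays.
#'
#' @param concentrations Trolox concentrations (µM), at least two distinct.
#' @param responses Responses, same length.
#' @return An object of class `aox_calibration`: slope, intercept,
#'   `r_squared`, `n_points`, and the underlying `lm` fit. Supports
#'   [tidy()], [glance()] and `autoplot()`.
#' @examples
#' fit_calibration(1:10, 0.02 * (1:10) + 0.01)
#' @export
fit_calibration <- function(concentrations, responses) {
  if (length(concentrations) != length(responses)) abort("length mismatch")
  if (length(unique(concentrations)) < 2) {
    abort("calibration needs at least 2 distinct concentrations")
  }
  fit <- stats::lm(responses ~ concentrations)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((responses - mean(responses))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = r2,
      n_points = length(responses),
      data = tibble::tibble(concentration = concentrations, response = responses),
      fit = fit
    ),
    class = "aox_calibration"
  )
}

#' @export
print.aox_calibration <- function(x, ...) {
  cat(sprintf(
    "Trolox calibration: response = %.6g * conc + %.6g (R^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n_points
  ))
  invisible(x)
}

#' Convert a response to trolox equivalents
#'
#' Inverts the calibration line and normalizes by the sample concentration:
#' `((response - intercept)/slope) / sample_conc`, giving the antioxidant
#' capacity in µmol trolox equivalents per µmol of sample.
#'
#' @param response Assay response(s).
#' @param model An [fit_calibration()] object.
#' @param sample_conc Final in-well sample concentration(s), µM, positive.
#' @return AOC in µmol TE/µmol.
#' @export
aoc_trolox_equivalents <- function(response, model, sample_conc) {
  if (!inherits(model, "aox_calibration")) abort("model must be an aox_calibration")
  if (model$slope == 0) abort("calibration slope is zero: AOC undefined")
  if (any(sample_conc <= 0)) abort("sample concentration must be positive")
  ((response - model$intercept) / model$slope) / sample_conc
}

#' Final in-well concentration
#'
#' Helper for the usual plate layout where a small volume of stock is added
#' to the reaction mix (e.g. 20 µL into a 200 µL well).
#'
#' @param stock_conc Stock concentration (µM).
#' @param vol_added Volume of stock added (µL).
#' @param vol_total Total well volume (µL).
#' @return Final concentration (µM).
#' @examples
#' final_concentration(100, 20, 200) # 10
#' @export
final_concentration <- function(stock_conc, vol_added = 20, vol_total = 200) {
  if (any(vol_total <= 0) || any(vol_added < 0)) abort("invalid volumes")
  stock_conc * vol_added / vol_total
}

# validate a long-format plate table and sort within wells
validate_plate <- function(plate, time_unit = c("min", "s")) {
  time_unit <- match.arg(time_unit)
  plate <- tibble::as_tibble(plate)
  need <- c("well", "sample_id", "role", "conc_um", "time", "signal")
  missing <- setdiff(need, names(plate))
  if (length(missing) > 0) {
    abort(paste0("plate table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  bad_role <- setdiff(unique(plate$role), c("sample", "blank", "calibrant", "control"))
  if (length(bad_role) > 0) {
    abort(paste0("unknown role(s): ", paste(bad_role, collapse = ", ")))
  }
  if (time_unit == "s") plate$time <- plate$time / 60
  dup <- duplicated(plate[, c("well", "time")])
  if (any(dup)) {
    d <- plate[dup, ][1, ]
    abort(sprintf("duplicate time point %.6g in well '%s'", d$time, d$well))
  }
  plate <- dplyr::arrange(plate, .data$well, .data$time)
  split(seq_len(nrow(plate)), plate$well) |>
    purrr::walk(function(idx) check_curve(plate$time[idx], plate$signal[idx]))
  plate
}

well_summary <- function(plate) {
  dplyr::distinct(plate[, c("well", "sample_id", "role", "conc_um")])
}

#' Quantify ORAC antioxidant capacity from a kinetic plate
#'
#' Full ORAC pipeline over a long-format plate table: per-well normalized
#' AUC of the fluorescein decay, net AUC relative to the mean blank, trolox
#' calibration (net AUC vs concentration over the calibrant wells), and
#' per-sample AOC in µmol TE/µmol.
#'
#' @param plate Long-format plate data: columns `well`, `sample_id`, `role`
#'   (`sample`/`blank`/`calibrant`/`control`), `conc_um` (final in-well µM),
#'   `time`, `signal`. See [read_plate_csv()] and [sim_orac_plate()].
#' @param time_unit `"min"` (default) or `"s"`.
#' @return An object of class `aox_assay` with elements `assay`,
#'   `calibration` (an `aox_calibration`), `wells` (per-well responses) and
#'   `samples` (per-sample tibble: `sample_id`, `conc_um`, `n_wells`, `aoc`,
#'   `aoc_sd`). [tidy()] returns the sample table; [glance()] the calibration
#'   summary.
#' @export
orac_aoc <- function(plate, time_unit = c("min", "s")) {
  plate <- validate_plate(plate, time_unit)
  wells <- well_summary(plate)
  wells$auc <- vapply(wells$well, function(w) {
    rows <- plate[plate$well == w, ]
    curve_auc(rows$time, rows$signal, normalize = TRUE)
  }, numeric(1))
  blanks <- wells$auc[wells$role == "blank"]
  if (length(blanks) == 0) abort("ORAC quantification needs at least one blank well")
  wells$response <- wells$auc - mean(blanks)
  finish_assay(wells, assay = "ORAC")
}

#' Quantify TEAC antioxidant capacity from a kinetic plate
#'
#' Full TEAC pipeline: per-well OD decline at `t_read` relative to the mean
#' control reading, trolox calibration of the decline, per-sample AOC.
#'
#' @inheritParams orac_aoc
#' @param t_read Read time (minutes) at which the absorbance decline is taken.
#' @return An `aox_assay` object, see [orac_aoc()].
#' @export
teac_aoc <- function(plate, t_read = 40.5, time_unit = c("min", "s")) {
  plate <- validate_plate(plate, time_unit)
  wells <- well_summary(plate)
  wells$od_read <- vapply(wells$well, function(w) {
    rows <- plate[plate$well == w, ]
    interp_at(rows$time, rows$signal, t_read)
  }, numeric(1))
  controls <- wells$od_read[wells$role == "control"]
  if (length(controls) == 0) abort("TEAC quantification needs at least one control well")
  wells$response <- mean(controls) - wells$od_read
  finish_assay(wells, assay = "TEAC")
}

finish_assay <- function(wells, assay) {
  cal_rows <- wells[wells$role == "calibrant", ]
  if (nrow(cal_rows) < 2) abort("need at least 2 calibrant wells")
  model <- fit_calibration(cal_rows$conc_um, cal_rows$response)
  samp <- wells[wells$role == "sample", ]
  samp$aoc_well <- aoc_trolox_equivalents(samp$response, model, samp$conc_um)
  samples <- samp |>
    dplyr::group_by(.data$sample_id, .data$conc_um) |>
    dplyr::summarise(
      n_wells = dplyr::n(),
      aoc = mean(.data$aoc_well),
      aoc_sd = stats::sd(.data$aoc_well),
      .groups = "drop"
    )
  structure(
    list(assay = assay, calibration = model, wells = tibble::as_tibble(wells), samples = samples),
    class = "aox_assay"
  )
}

#' @export
print.aox_assay <- function(x, ...) {
  cat(sprintf("%s assay quantification (%d wells)\n", x$assay, nrow(x$wells)))
  print(x$calibration)
  print(x$samples)
  invisible(x)
}
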