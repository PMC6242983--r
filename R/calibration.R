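# Fluorescein PMT calibration and intensity normalization.
#
# PMT gain varies as a power law of the applied voltage. Imaging fluorescein
# standards of known concentration across voltages gives, after dividing out
# laser power and concentration, a log-log-linear relationship whose slope is
# the gain exponent. Raw intensities acquired at arbitrary (power, voltage)
# settings are then converted to uM-fluorescein-equivalent units, making
# acquisitions across days and settings directly comparable.

#' Fit the PMT power-law calibration
#'
#' Least-squares fit of \code{log(intensity / (laser_power * concentration))}
#' against \code{log(voltage)}.
#'
#' @param series a \code{\link{generate_calibration_series}} data frame, or
#'   any data frame with columns \code{concentration}, \code{pmt_voltage},
#'   \code{laser_power}, \code{intensity}
#' @return object of class \code{pmt_calibration}: \code{prefactor},
#'   \code{exponent}, \code{fit_r2}, \code{voltage_range}
#' @export
fit_pmt_calibration <- function(series) {
  req <- c("concentration", "pmt_voltage", "laser_power", "intensity")
  stopifnot(all(req %in% names(series)))
  if (length(unique(series$pmt_voltage)) < 3)
    stop("need at least 3 distinct PMT voltages")
  if (any(series$intensity <= 0))
    stop("non-positive intensities cannot be calibrated")
  y <- log(series$intensity / (series$laser_power * series$concentration))
  x <- log(series$pmt_voltage)
  fit <- stats::lm(y ~ x)
  structure(list(prefactor = exp(stats::coef(fit)[[1]]),
                 exponent = stats::coef(fit)[[2]],
                 fit_r2 = suppressWarnings(summary(fit)$r.squared),
                 voltage_range = range(series$pmt_voltage)),
            class = "pmt_calibration")
}

#' @export
print.pmt_calibration <- function(x, ...) {
  cat(sprintf("PMT calibration: intensity = %.3g * conc * V^%.3f * power (r2 = %.4f)\n",
              x$prefactor, x$exponent, x$fit_r2))
  invisible(x)
}

#' Normalize raw intensities by laser power and calibrated PMT gain
#'
#' \code{normalized = raw / (laser_power * prefactor * voltage^exponent)},
#' in uM-fluorescein-equivalent units. Two acquisitions of the same scene at
#' different settings normalize to equal values (within noise).
#'
#' @param volume raw intensity array
#' @param laser_power mW
#' @param pmt_voltage V; a voltage outside the calibrated range triggers a
#'   warning (extrapolation) but is still computed
#' @param model a \code{\link{fit_pmt_calibration}} model
#' @return normalized array with the dimensions of \code{volume}
#' @export
normalize_stack <- function(volume, laser_power, pmt_voltage, model) {
  stopifnot(inherits(model, "pmt_calibration"),
            laser_power > 0, pmt_voltage > 0)
  if (pmt_voltage < model$voltage_range[1] ||
      pmt_voltage > model$voltage_range[2])
    warning("PMT voltage outside calibrated range; extrapolating the gain law")
  volume / (laser_power * model$prefactor * pmt_voltage^model$exponent)
}
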