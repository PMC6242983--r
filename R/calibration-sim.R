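# Synthetic fluorescein calibration series.

#' Generate a fluorescein PMT-calibration series
#'
#' Emulates imaging fluorescein standards (0.1-20 uM) across PMT voltages and
#' laser powers. Mean intensity follows the power-law gain model
#' \code{prefactor * concentration * voltage^exponent * laser_power},
#' multiplied by lognormal noise with coefficient of variation
#' \code{noise_cv}.
#'
#' @param prefactor gain-law scale
#' @param exponent power on PMT voltage (> 0)
#' @param voltages PMT voltages, V
#' @param concentrations fluorescein concentrations, uM
#' @param laser_power mW (scalar, recycled)
#' @param noise_cv lognormal noise CV (>= 0)
#' @param seed RNG seed
#' @return data frame of class \code{calibration_series} with columns
#'   \code{concentration}, \code{pmt_voltage}, \code{laser_power},
#'   \code{intensity}
#' @export
generate_calibration_series <- function(prefactor = 1e-18, exponent = 6,
                                        voltages = seq(600, 900, by = 50),
                                        concentrations = c(0.1, 0.5, 1, 2, 5,
                                                           10, 20),
                                        laser_power = 10,
                                        noise_cv = 0.03, seed = 1L) {
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (exponent <= 0) stop("exponent must be positive")
  if (length(voltages) == 0 || length(concentrations) == 0)
    stop("voltages and concentrations must be non-empty")
  g <- expand.grid(concentration = concentrations, pmt_voltage = voltages)
  g$laser_power <- laser_power
  mu <- prefactor * g$concentration * g$pmt_voltage^exponent * g$laser_power
  if (noise_cv > 0) {
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    mu <- mu * stats::rlnorm(nrow(g), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  g$intensity <- mu
  class(g) <- c("calibration_series", class(g))
  g
}
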