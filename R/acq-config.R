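#' Acquisition configuration for the synthetic multiphoton experiment
#'
#' Describes the geometry and timing of one wound-edge acquisition: repeated
#' three-channel z-stacks (NADH 755/460, FAD+keratin 900/525, collagen SHG
#' 900/460) and TCSPC lifetime imaging under 80 MHz pulsed excitation.
#'
#' The study acquisition is 512 x 512 pixels over a 584 x 584 um field, 5 um
#' z-steps down to 250 um, and 50 sequential stacks per location. The default
#' here is a reduced geometry (128 x 128, 11 slices, 10 repeats) sized for
#' desk-scale tests; pass the full values to emulate the study acquisition.
#'
#' @param image_size integer 2-vector, pixels (y, x)
#' @param field_of_view numeric 2-vector, um
#' @param z_step z increment, um
#' @param z_depth total depth, um; must be an integer multiple of \code{z_step}
#' @param n_repeats number of sequential stacks per location (>= 2)
#' @param laser_period_ns excitation period, ns (12.5 ns = 80 MHz)
#' @param tcspc_bins number of TCSPC time bins
#' @param tcspc_bin_width_ps bin width, ps; defaults to
#'   \code{laser_period_ns * 1000 / tcspc_bins}
#' @param seed integer RNG seed recorded with the configuration
#' @return an object of class \code{acq_config}
#' @export
acq_config <- function(image_size = c(128L, 128L),
                       field_of_view = c(584, 584),
                       z_step = 5, z_depth = 50,
                       n_repeats = 10L,
                       laser_period_ns = 12.5,
                       tcspc_bins = 64L,
                       tcspc_bin_width_ps = NULL,
                       seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 8),
            z_step > 0, z_depth >= 0)
  if (n_repeats < 2) stop("n_repeats must be >= 2")
  if (laser_period_ns <= 0) stop("laser_period_ns must be positive")
  if (abs(z_depth / z_step - round(z_depth / z_step)) > 1e-9)
    stop("z_depth must be an integer multiple of z_step")
  if (is.null(tcspc_bin_width_ps))
    tcspc_bin_width_ps <- laser_period_ns * 1000 / tcspc_bins
  structure(list(
    image_size = as.integer(image_size),
    field_of_view = field_of_view,
    z_step = z_step, z_depth = z_depth,
    n_slices = as.integer(round(z_depth / z_step)) + 1L,
    n_repeats = as.integer(n_repeats),
    channels = c("NADH", "FAD", "SHG"),
    laser_period_ns = laser_period_ns,
    tcspc_bins = as.integer(tcspc_bins),
    tcspc_bin_width_ps = tcspc_bin_width_ps,
    seed = as.integer(seed)
  ), class = "acq_config")
}

#' @export
print.acq_config <- function(x, ...) {
  cat(sprintf("acq_config: %d x %d px (%g x %g um), %d slices of %g um, %d repeats\n",
              x$image_size[1], x$image_size[2], x$field_of_view[1], x$field_of_view[2],
              x$n_slices, x$z_step, x$n_repeats))
  cat(sprintf("  laser period %g ns (%.0f MHz), %d TCSPC bins of %.2f ps\n",
              x$laser_period_ns, 1000 / x$laser_period_ns,
              x$tcspc_bins, x$tcspc_bin_width_ps))
  invisible(x)
}
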