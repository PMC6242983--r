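# Procedural wound-edge scene with known metabolic ground truth.
#
# The scene is a 2.5-D procedural texture, not a light-transport simulation:
# an epithelial compartment of NADH-bright ellipsoidal cells advancing as a
# tongue over a dim wound bed, intact dermis with an oriented collagen fiber
# field carrying the SHG channel, and optional hair-follicle occluders. The
# NADH and FAD channels are constructed from a shared radiance field L and the
# true redox field R as NADH = L*(1-R), FAD = L*R, so the pixel-wise ratio
# FAD/(NADH+FAD) of the noiseless volume reproduces R to machine precision.

#' Scene parameters for the synthetic wound edge
#'
#' @param edge_frac fraction of the x axis where the intact dermis ends and
#'   the wound bed begins (the base of the epithelial tongue)
#' @param tip_frac fraction of the x axis reached by the tongue tip
#' @param epi_thick_frac fraction of z slices occupied by epithelium
#' @param redox_base,redox_tip ground-truth optical redox ratio
#'   FAD/(NADH+FAD) at the base and tip of the tongue
#' @param redox_profile \code{"ramp"} (uniform basal and distal thirds joined
#'   by a linear transition; the regional means equal the endpoint values) or
#'   \code{"linear"} (straight gradient from base to tip)
#' @param plateau_frac plateau width as a fraction of the tongue axis for the
#'   ramp profile
#' @param epi_level epithelial NADH+FAD radiance, uM-fluorescein-equivalent
#' @param dermis_level,wound_level autofluorescence radiance of dermis and
#'   wound bed
#' @param dermis_redox,wound_redox redox ratio assigned outside the epithelium
#' @param shg_level SHG radiance of dermal collagen fibers
#' @param cell_density epithelial cells per pixel of epithelial area
#' @param cell_radius_px cell radius, pixels
#' @param n_follicles hair-follicle occluders placed in the dermis
#' @param depth_atten_um 1/e length of the exponential signal attenuation with
#'   depth applied to every channel (ratio-preserving)
#' @return a list of scene parameters
#' @export
wound_scene_params <- function(edge_frac = 0.35, tip_frac = 0.85,
                               epi_thick_frac = 0.35,
                               redox_base = 0.35, redox_tip = 0.6,
                               redox_profile = c("ramp", "linear"),
                               plateau_frac = 1 / 3,
                               epi_level = 100, dermis_level = 30,
                               wound_level = 4,
                               dermis_redox = 0.45, wound_redox = 0.5,
                               shg_level = 120,
                               cell_density = 0.01, cell_radius_px = 4,
                               n_follicles = 0,
                               depth_atten_um = 150) {
  redox_profile <- match.arg(redox_profile)
  stopifnot(edge_frac > 0, tip_frac <= 1, epi_thick_frac > 0,
            redox_base >= 0, redox_base <= 1, redox_tip >= 0, redox_tip <= 1,
            epi_level > 0, depth_atten_um > 0)
  as.list(environment())
}

# Redox value along the tongue axis u in [0, 1].
tongue_redox_profile <- function(u, scene) {
  lo <- scene$redox_base; hi <- scene$redox_tip
  if (scene$redox_profile == "linear") return(lo + (hi - lo) * u)
  p <- scene$plateau_frac
  v <- (pmin(pmax(u, p), 1 - p) - p) / (1 - 2 * p)
  lo + (hi - lo) * v
}

#' Generate the noiseless three-channel wound-edge volume
#'
#' Builds the "true" scene that downstream acquisition noise and motion are
#' layered onto, together with a ground-truth record of the epithelial mask
#' and per-voxel redox field.
#'
#' @param config an \code{\link{acq_config}}
#' @param scene a list from \code{\link{wound_scene_params}}
#' @param seed RNG seed for cell/fiber placement (defaults to the config seed)
#' @return a list of class \code{wound_volume} with elements
#'   \code{channels} (named list of \code{[y, x, z]} arrays NADH, FAD, SHG),
#'   \code{truth} (class \code{mpm_truth}: \code{epithelial_mask},
#'   \code{tongue_mask}, \code{true_redox_field}, \code{tongue_u},
#'   \code{artifact_frames}), \code{config} and \code{scene}
#' @export
generate_wound_edge_volume <- function(config, scene = wound_scene_params(),
                                       seed = config$seed) {
  ny <- config$image_size[1]; nx <- config$image_size[2]
  nz <- config$n_slices
  edge_x <- round(scene$edge_frac * nx)
  tip_x <- round(scene$tip_frac * nx)
  epi_nz <- max(1L, round(scene$epi_thick_frac * nz))
  if (tip_x <= edge_x || tip_x < 2)
    stop("degenerate geometry: epithelial tongue is empty")

  set.seed(seed)
  # epithelial cellular texture (shared across z with small per-slice jitter)
  n_cells <- max(1L, round(scene$cell_density * ny * tip_x))
  cy <- runif(n_cells, 1, ny); cx <- runif(n_cells, 1, tip_x)
  r <- scene$cell_radius_px
  cell_field <- matrix(0, ny, nx)
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  for (i in seq_len(n_cells)) {
    d2 <- (yy - cy[i])^2 + (xx - cx[i])^2
    cell_field <- cell_field + exp(-d2 / (2 * (r / 1.5)^2))
  }
  cell_field <- cell_field / max(cell_field)

  blob_field <- function(n_blobs, radius) {
    by <- runif(n_blobs, 1, ny); bx <- runif(n_blobs, 1, nx)
    f <- matrix(0, ny, nx)
    for (i in seq_len(n_blobs)) {
      d2 <- (yy - by[i])^2 + (xx - bx[i])^2
      f <- f + exp(-d2 / (2 * radius^2))
    }
    f / max(f)
  }

  # dermal fiber field for SHG: oriented sinusoidal streaks under a smooth
  # random envelope (the envelope breaks the translational self-similarity
  # of the bare sinusoid)
  th <- runif(1, 0, pi)
  fiber <- 0.5 + 0.5 * sin(2 * pi * (cos(th) * yy + sin(th) * xx) / (3 * r)) *
    sin(2 * pi * (cos(th + pi / 2) * yy + sin(th + pi / 2) * xx) / (12 * r))
  fiber <- pmax(fiber, 0) *
    (0.35 + 0.65 * blob_field(max(1L, round(0.005 * ny * nx)), 2.5 * r))

  # granulation/interstitial texture so dermis and wound bed are not flat
  gran <- blob_field(max(1L, round(0.02 * ny * nx)), r / 2)

  epi2d <- xx <= tip_x                       # epithelium present (x extent)
  tongue2d <- epi2d & xx >= edge_x
  dermis2d <- xx <= edge_x
  u2d <- pmin(pmax((xx - edge_x) / (tip_x - edge_x), 0), 1)
  redox2d <- matrix(scene$wound_redox, ny, nx)
  redox2d[dermis2d] <- scene$dermis_redox
  redox2d[epi2d] <- tongue_redox_profile(u2d[epi2d], scene)

  if (scene$n_follicles > 0) {
    fy <- runif(scene$n_follicles, 1, ny)
    fx <- runif(scene$n_follicles, 1, edge_x)
  }

  zs <- (seq_len(nz) - 1L) * config$z_step
  atten <- exp(-zs / scene$depth_atten_um)
  mk <- function() array(0, dim = c(ny, nx, nz))
  nadh <- mk(); fad <- mk(); shg <- mk()
  epi_mask <- array(FALSE, dim = c(ny, nx, nz))
  tongue_mask <- array(FALSE, dim = c(ny, nx, nz))
  redox <- array(NA_real_, dim = c(ny, nx, nz))
  u3 <- array(NA_real_, dim = c(ny, nx, nz))

  for (k in seq_len(nz)) {
    in_epi_z <- k <= epi_nz
    L <- scene$wound_level * (0.4 + 1.2 * gran)
    L[dermis2d] <- scene$dermis_level * (0.35 + 0.9 * fiber[dermis2d] +
                                           0.4 * gran[dermis2d])
    s <- matrix(0, ny, nx)
    if (in_epi_z) {
      L[epi2d] <- scene$epi_level * (0.4 + 0.9 * cell_field[epi2d])
      epi_mask[, , k] <- epi2d
      tongue_mask[, , k] <- tongue2d
    } else {
      s[dermis2d] <- scene$shg_level * fiber[dermis2d]
    }
    if (scene$n_follicles > 0 && !in_epi_z) {
      for (i in seq_len(scene$n_follicles)) {
        d2 <- (yy - fy[i])^2 + (xx - fx[i])^2
        foc <- d2 < (3 * r)^2
        L[foc] <- scene$epi_level          # NADH-bright follicle, no SHG
        s[foc] <- 0
      }
    }
    Rk <- redox2d
    nadh[, , k] <- atten[k] * L * (1 - Rk)
    fad[, , k] <- atten[k] * L * Rk
    shg[, , k] <- atten[k] * s
    redox[, , k] <- Rk
    u3[, , k] <- ifelse(epi_mask[, , k], u2d, NA_real_)
  }

  truth <- structure(list(
    epithelial_mask = epi_mask,
    tongue_mask = tongue_mask,
    true_redox_field = redox,
    tongue_u = u3,
    artifact_frames = data.frame(repeat_idx = integer(), depth = integer())
  ), class = "mpm_truth")

  structure(list(channels = list(NADH = nadh, FAD = fad, SHG = shg),
                 truth = truth, config = config, scene = scene),
            class = "wound_volume")
}

#' Basal / middle / distal thirds of the epithelial tongue
#'
#' Partitions the tongue voxels by the normalized base-to-tip coordinate u
#' into thirds, for regional redox summaries.
#' @param truth an \code{mpm_truth} from \code{\link{generate_wound_edge_volume}}
#' @return named list of three logical arrays (basal, middle, distal)
#' @export
tongue_region_masks <- function(truth) {
  u <- truth$tongue_u
  m <- truth$tongue_mask
  list(basal = m & !is.na(u) & u < 1 / 3,
       middle = m & !is.na(u) & u >= 1 / 3 & u <= 2 / 3,
       distal = m & !is.na(u) & u > 2 / 3)
}

#' Render a noiseless radiance volume as detector counts
#'
#' Applies the acquisition transfer function: counts = radiance * laser_power
#' * prefactor * voltage^exponent, then Poisson shot noise and additive
#' Gaussian read noise. The same power-law gain model is what the fluorescein
#' calibration recovers, closing the loop with \code{\link{normalize_stack}}.
#'
#' @param volume radiance array (any dimensionality) in
#'   uM-fluorescein-equivalent units
#' @param laser_power mW
#' @param pmt_voltage V
#' @param prefactor,exponent true PMT gain law parameters
#' @param read_noise_sd Gaussian read noise sd, counts
#' @param seed RNG seed; \code{NULL} leaves the RNG stream untouched
#' @param noiseless if TRUE return the expected counts without noise
#' @return array of counts with the dimensions of \code{volume}
#' @export
render_acquisition <- function(volume, laser_power, pmt_voltage,
                               prefactor = 1e-18, exponent = 6,
                               read_noise_sd = 2, seed = NULL,
                               noiseless = FALSE) {
  stopifnot(laser_power > 0, pmt_voltage > 0, prefactor > 0)
  mu <- volume * laser_power * prefactor * pmt_voltage^exponent
  if (noiseless) return(mu)
  if (!is.null(seed)) set.seed(seed)
  out <- stats::rpois(length(mu), lambda = as.numeric(mu)) +
    stats::rnorm(length(mu), 0, read_noise_sd)
  array(pmax(out, 0), dim = dim(mu))
}
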