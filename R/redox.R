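# Optical redox ratio mapping and epithelial summaries.

#' Per-pixel optical redox ratio map
#'
#' \code{FAD / (NADH + FAD)} from co-registered normalized channel volumes.
#' Pixels whose summed intensity does not exceed the floor are marked invalid
#' (the ratio is undefined at vanishing signal) and never enter summaries.
#' Non-negative inputs guarantee values in [0, 1]; no clipping is applied.
#'
#' @param nadh_norm,fad_norm normalized intensity arrays of identical shape
#' @param floor intensity floor; default 1 percent of the 99th percentile of
#'   the normalized NADH volume
#' @param epithelial_mask optional logical array carried along for summaries
#' @return object of class \code{redox_map}: \code{values} (NA where invalid),
#'   \code{valid}, \code{epithelial_mask}, \code{floor}
#' @export
compute_redox_map <- function(nadh_norm, fad_norm, floor = NULL,
                              epithelial_mask = NULL) {
  if (!all(dim(nadh_norm) == dim(fad_norm)))
    stop("channel volumes must be co-registered with identical shape")
  if (any(nadh_norm < 0) || any(fad_norm < 0))
    stop("negative input intensities")
  if (is.null(floor))
    floor <- 0.01 * stats::quantile(nadh_norm, 0.99, names = FALSE)
  total <- nadh_norm + fad_norm
  valid <- total > floor
  values <- ifelse(valid, fad_norm / total, NA_real_)
  values <- array(values, dim = dim(nadh_norm))
  structure(list(values = values, valid = valid,
                 epithelial_mask = epithelial_mask, floor = floor),
            class = "redox_map")
}

#' Depth-slice indices at 1/4, 1/2 and 3/4 of the stack
#'
#' One-based indices of the slices at the three quarter depths, using the
#' half-up rounding of \code{round((k/4) * (n_slices - 1))} on the zero-based
#' axis (a 51-slice stack selects zero-based 13, 25, 38).
#' @param n_slices number of z slices
#' @return integer vector of length 3 (1-based)
#' @export
quarter_depth_indices <- function(n_slices) {
  as.integer(round_half_up((1:3) / 4 * (n_slices - 1)) + 1L)
}

#' Mean epithelial redox ratio at the three quarter depths
#'
#' Pools every valid masked pixel from the slices at 1/4, 1/2 and 3/4 total
#' stack depth and returns the pooled (pixel-weighted) mean; a mean-of-slice-
#' means variant is available via \code{pooled = FALSE}.
#'
#' @param map a \code{\link{compute_redox_map}} result
#' @param mask logical array; defaults to the map's epithelial mask
#' @param pooled pooled pixel mean (default) or mean of per-slice means
#' @return list with \code{mean}, \code{n_pixels}, \code{slices}
#' @export
mean_epithelial_redox <- function(map, mask = NULL, pooled = TRUE) {
  if (is.null(mask)) mask <- map$epithelial_mask
  if (is.null(mask)) stop("an epithelial mask is required")
  d <- dim(map$values)
  if (length(d) != 3) stop("mean_epithelial_redox expects a z-stack map")
  ks <- quarter_depth_indices(d[3])
  per_slice <- lapply(ks, function(k) {
    sel <- mask[, , k] & map$valid[, , k]
    map$values[, , k][sel]
  })
  n <- vapply(per_slice, length, integer(1))
  if (sum(n) == 0) stop("epithelial mask empty at the three quarter depths")
  m <- if (pooled) mean(unlist(per_slice))
  else mean(vapply(per_slice[n > 0], mean, numeric(1)))
  list(mean = m, n_pixels = sum(n), slices = ks)
}

#' Mean redox ratio within an arbitrary region
#'
#' @param map a \code{redox_map}
#' @param region logical array matching the map
#' @return list with \code{mean} and \code{n_pixels}
#' @export
region_mean_redox <- function(map, region) {
  sel <- region & map$valid
  v <- map$values[sel]
  if (length(v) == 0) stop("region contains no valid pixels")
  list(mean = mean(v), n_pixels = length(v))
}

#' Map redox values to a rainbow lookup table for rendering
#'
#' Fixed [0, 1] range; invalid pixels render black.
#' @param values redox matrix (one slice)
#' @param n_colors LUT size
#' @return character matrix of hex colors
#' @export
redox_lut <- function(values, n_colors = 256L) {
  pal <- grDevices::hcl.colors(n_colors, "Spectral", rev = TRUE)
  idx <- pmin(pmax(floor(values * n_colors) + 1L, 1L), n_colors)
  out <- matrix(pal[idx], nrow(values), ncol(values))
  out[is.na(values)] <- "#000000"
  out
}
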