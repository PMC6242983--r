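# Synthetic Ki67 / DAPI section images with known co-localization.

#' Generate a two-channel Ki67/DAPI nuclei image
#'
#' Places \code{n_nuclei} non-overlapping Gaussian-blob nuclei at random; the
#' DAPI channel shows all of them, the Ki67 channel shows
#' \code{round(coloc_fraction * n_nuclei)} of the same nuclei. The ground
#' truth records which nuclei are Ki67-positive.
#'
#' @param n_nuclei number of nuclei
#' @param coloc_fraction fraction of nuclei that are Ki67-positive, in [0, 1]
#' @param image_size pixels (y, x)
#' @param nucleus_radius blob radius, px
#' @param background background level of both channels
#' @param noise_sd additive Gaussian noise sd
#' @param seed RNG seed
#' @param max_tries placement retries before declaring overcrowding
#' @return list of class \code{histology_image} with \code{dapi}, \code{ki67}
#'   matrices and \code{truth} (\code{centers}, \code{ki67_positive},
#'   \code{coloc_fraction})
#' @export
generate_histology_image <- function(n_nuclei, coloc_fraction,
                                     image_size = c(256L, 256L),
                                     nucleus_radius = 5, background = 0.05,
                                     noise_sd = 0.02, seed = 1L,
                                     max_tries = 2000L) {
  if (coloc_fraction < 0 || coloc_fraction > 1)
    stop("coloc_fraction must be in [0, 1]")
  set.seed(seed)
  ny <- image_size[1]; nx <- image_size[2]
  min_sep <- 3 * nucleus_radius
  centers <- matrix(NA_real_, n_nuclei, 2)
  placed <- 0L; tries <- 0L
  margin <- 2 * nucleus_radius
  while (placed < n_nuclei) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place nuclei without overlap (overcrowded image)")
    cand <- c(stats::runif(1, margin, ny - margin),
              stats::runif(1, margin, nx - margin))
    if (placed == 0L ||
        min((centers[seq_len(placed), 1] - cand[1])^2 +
              (centers[seq_len(placed), 2] - cand[2])^2) >= min_sep^2) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
  }
  n_pos <- round(coloc_fraction * n_nuclei)
  pos <- rep(FALSE, n_nuclei)
  pos[sample.int(n_nuclei, n_pos)] <- TRUE

  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  blob <- function(which_nuclei) {
    im <- matrix(background, ny, nx)
    for (i in which_nuclei) {
      d2 <- (yy - centers[i, 1])^2 + (xx - centers[i, 2])^2
      im <- im + exp(-d2 / (2 * (nucleus_radius / 1.6)^2))
    }
    im + stats::rnorm(length(im), 0, noise_sd)
  }
  dapi <- blob(seq_len(n_nuclei))
  ki67 <- blob(which(pos))

  structure(list(dapi = dapi, ki67 = ki67,
                 truth = list(centers = centers, ki67_positive = pos,
                              coloc_fraction = coloc_fraction,
                              nucleus_radius = nucleus_radius)),
            class = "histology_image")
}
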