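# Motion/noise corruption of the repeated z-stack acquisition.

#' Default artifact model for corrupted frames
#'
#' Three artifact classes, each chosen to depress the frame's normalized
#' cross-correlation against the stack average: a whole-frame translation
#' larger than the registration search window, an intra-frame shear (rows
#' progressively displaced, as produced by motion during a resonant-scanned
#' frame), and an intensity dropout where the frame is mostly detector noise.
#'
#' @param types artifact classes to draw from
#' @param shift_range inclusive integer range of large-shift magnitudes, px;
#'   \code{NULL} (default) scales with the frame: 25-45 percent of the
#'   smaller frame dimension, never below 10 px (respiration-scale motion
#'   displaces the whole field of view)
#' @param shear_frac total row displacement across the frame for shear, as a
#'   fraction of frame width
#' @param dropout_factor signal multiplier for dropout frames
#' @return list of artifact-model parameters
#' @export
artifact_model <- function(types = c("shift", "shear", "dropout"),
                           shift_range = NULL,
                           shear_frac = 0.5, dropout_factor = 0.05) {
  list(types = types, shift_range = shift_range,
       shear_frac = shear_frac, dropout_factor = dropout_factor)
}

apply_shear <- function(img, shear_px) {
  ny <- nrow(img)
  out <- img
  for (y in seq_len(ny))
    out[y, ] <- img[y, ((seq_len(ncol(img)) - 1L + round(shear_px * y / ny)) %%
                          ncol(img)) + 1L]
  out
}

#' Emit a repeated, noise- and motion-corrupted stack sequence
#'
#' Each of the \code{n_repeats} copies of every depth slice receives Poisson
#' shot noise, Gaussian read noise and a small random whole-frame jitter
#' (uniform on -2..2 px, circular so registration can recover it exactly).
#' With probability \code{artifact_prob} a frame is additionally corrupted by
#' one of the \code{\link{artifact_model}} classes; corrupted (repeat, depth)
#' pairs are recorded in the ground truth.
#'
#' Reproducibility contract: the corruption mask is the first draw from
#' \code{set.seed(seed)} — \code{runif(n_repeats * n_slices) < artifact_prob}
#' filled repeat-major — so the seeded binomial count is recomputable, and the
#' whole sequence is bit-identical for identical inputs and seed.
#'
#' @param volume a \code{wound_volume}, a single \code{[y, x, z]} array, or a
#'   named list of such arrays (channels share the same motion, independent
#'   noise)
#' @param config an \code{\link{acq_config}}
#' @param artifact_prob per-frame corruption probability in [0, 1)
#' @param model an \code{\link{artifact_model}}
#' @param read_noise_sd Gaussian read noise sd, counts
#' @param jitter_px max small-jitter magnitude applied to all frames
#' @param seed RNG seed
#' @return object of class \code{repeat_stack_seq}: \code{channels} (named
#'   list of \code{[y, x, z, repeat]} arrays), \code{artifact_frames} (data
#'   frame with \code{repeat_idx}, \code{depth}, \code{type}), \code{jitter}
#'   (\code{[2, z, repeat]} array of applied small shifts), \code{config}
#' @export
inject_motion_artifacts <- function(volume, config, artifact_prob = 0.08,
                                    model = artifact_model(),
                                    read_noise_sd = 2, jitter_px = 2L,
                                    seed = config$seed) {
  if (artifact_prob >= 1 || artifact_prob < 0)
    stop("artifact_prob must be in [0, 1)")
  if (inherits(volume, "wound_volume")) volume <- volume$channels
  if (!is.list(volume)) volume <- list(ch1 = volume)
  d <- dim(volume[[1]])
  stopifnot(length(d) == 3)
  nz <- d[3]; nrep <- config$n_repeats

  if (is.null(model$shift_range)) {
    lo <- max(10L, round(0.25 * min(d[1], d[2])))
    model$shift_range <- c(lo, max(lo + 2L, round(0.45 * min(d[1], d[2]))))
  }

  set.seed(seed)
  corrupt <- matrix(stats::runif(nrep * nz) < artifact_prob, nrep, nz)
  jit <- array(sample(seq(-jitter_px, jitter_px), 2 * nz * nrep, replace = TRUE),
               dim = c(2, nz, nrep))
  art <- data.frame(repeat_idx = integer(), depth = integer(),
                    type = character())
  art_spec <- vector("list", sum(corrupt))
  ix <- 0L
  for (r in seq_len(nrep)) for (k in seq_len(nz)) if (corrupt[r, k]) {
    ix <- ix + 1L
    ty <- sample(model$types, 1L)
    sh <- sample(seq(model$shift_range[1], model$shift_range[2]), 2L,
                 replace = TRUE) * sample(c(-1L, 1L), 2L, replace = TRUE)
    art_spec[[ix]] <- list(r = r, k = k, type = ty, shift = sh)
    art <- rbind(art, data.frame(repeat_idx = r, depth = k, type = ty))
  }

  out <- lapply(volume, function(v) array(0, dim = c(d[1], d[2], nz, nrep)))
  for (r in seq_len(nrep)) for (k in seq_len(nz)) {
    dyx <- jit[, k, r]
    spec <- NULL
    if (corrupt[r, k])
      spec <- art_spec[[which(vapply(art_spec, function(s)
        s$r == r && s$k == k, logical(1)))[1]]]
    for (ch in names(volume)) {
      fr <- circ_shift(volume[[ch]][, , k], dyx[1], dyx[2])
      if (!is.null(spec)) {
        if (spec$type == "shift") fr <- circ_shift(fr, spec$shift[1], spec$shift[2])
        if (spec$type == "shear")
          fr <- apply_shear(fr, round(model$shear_frac * d[2]))
        if (spec$type == "dropout") fr <- fr * model$dropout_factor
      }
      fr <- stats::rpois(length(fr), as.numeric(fr)) +
        stats::rnorm(length(fr), 0, read_noise_sd)
      out[[ch]][, , k, r] <- pmax(fr, 0)
    }
  }

  structure(list(channels = out, artifact_frames = art, jitter = jit,
                 artifact_prob = artifact_prob, config = config, seed = seed),
            class = "repeat_stack_seq")
}
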