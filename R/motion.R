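# Frame rejection and registration of repeated wound-edge z-stacks.
#
# Processing follows the acquisition design: the 50 (here n_repeats) stacks of
# one excitation and location are averaged per depth into an initial reference;
# every frame is registered to its reference slice by normalized 2D
# cross-correlation; frames whose correlation maximum falls more than one
# standard deviation below the per-depth mean are discarded; survivors are
# shifted into register and averaged; finally the two excitation channels are
# aligned by 3D cross-correlation.
#
# Correlation is the Pearson form, defined by the spatial-domain sum over the
# overlap region of each candidate shift (zero-mean, unit-variance within the
# window), so a frame that is an exact translation of its reference scores
# exactly 1 at the true shift. The cross term is FFT-accelerated with
# zero-padding (no circular wrap-around); the window means/variances come from
# integral images. Registration is integer-pixel by design: the argmax is
# taken over a bounded search window, so the small acquisition jitter (a few
# px) is recoverable while large artifact shifts fall outside the window and
# score low.

#' Initial per-depth average of a repeat sequence
#'
#' Unweighted mean over repeats at each depth, with no registration applied.
#' @param frames \code{[y, x, z, repeat]} array, or a \code{repeat_stack_seq}
#'   (first channel used unless \code{channel} names another)
#' @param channel channel name when \code{frames} is a sequence
#' @return \code{[y, x, z]} reference array
#' @export
build_reference_average <- function(frames, channel = NULL) {
  frames <- get_channel_frames(frames, channel)
  d <- dim(frames)
  if (length(d) != 4) stop("frames must be a [y, x, z, repeat] array")
  if (d[4] < 2) stop("need at least 2 repeats")
  rowMeans(frames, dims = 3)
}

get_channel_frames <- function(x, channel = NULL) {
  if (inherits(x, "repeat_stack_seq")) {
    ch <- if (is.null(channel)) 1L else channel
    return(x$channels[[ch]])
  }
  x
}

# Integral image: I[i+1, j+1] = sum(m[1:i, 1:j]).
integral_image <- function(m) {
  out <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  out[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  out
}

rect_sum <- function(I, r0, r1, c0, c1) {
  I[r1 + 1L, c1 + 1L] - I[r0, c1 + 1L] - I[r1 + 1L, c0] + I[r0, c0]
}

# Windowed-Pearson cross-correlation surface of `frame` against `ref` over
# shifts |dy|,|dx| <= max_shift. Entry (dy, dx) is the Pearson correlation of
# the frame translated by (dy, dx) with the reference over their overlap.
# Returns NULL when either full image has zero variance.
ncc_surface <- function(frame, ref, max_shift) {
  if (stats::sd(frame) == 0 || stats::sd(ref) == 0) return(NULL)
  ny <- nrow(frame); nx <- ncol(frame)
  P <- ny + 2L * max_shift; Q <- nx + 2L * max_shift
  Fp <- matrix(0, P, Q); Rp <- matrix(0, P, Q)
  Fp[seq_len(ny), seq_len(nx)] <- frame
  Rp[seq_len(ny), seq_len(nx)] <- ref
  cc <- Re(stats::fft(stats::fft(Fp) * Conj(stats::fft(Rp)), inverse = TRUE)) /
    (P * Q)   # cc[(u mod P)+1, (v mod Q)+1] = sum frame[y+u, x+v] * ref[y, x]
  If <- integral_image(frame); If2 <- integral_image(frame^2)
  Ir <- integral_image(ref); Ir2 <- integral_image(ref^2)
  sh <- seq(-max_shift, max_shift)
  out <- matrix(NA_real_, length(sh), length(sh),
                dimnames = list(dy = sh, dx = sh))
  for (iy in seq_along(sh)) for (ix in seq_along(sh)) {
    dy <- sh[iy]; dx <- sh[ix]
    r0 <- 1L + max(dy, 0L); r1 <- ny + min(dy, 0L)
    c0 <- 1L + max(dx, 0L); c1 <- nx + min(dx, 0L)
    n <- (r1 - r0 + 1) * (c1 - c0 + 1)
    s_fr <- cc[((-dy) %% P) + 1L, ((-dx) %% Q) + 1L]
    s_f <- rect_sum(If, r0 - dy, r1 - dy, c0 - dx, c1 - dx)
    s_f2 <- rect_sum(If2, r0 - dy, r1 - dy, c0 - dx, c1 - dx)
    s_r <- rect_sum(Ir, r0, r1, c0, c1)
    s_r2 <- rect_sum(Ir2, r0, r1, c0, c1)
    vf <- s_f2 - s_f^2 / n
    vr <- s_r2 - s_r^2 / n
    out[iy, ix] <- if (vf <= 0 || vr <= 0) 0
    else (s_fr - s_f * s_r / n) / sqrt(vf * vr)
  }
  out
}

#' Register one frame to its reference slice
#'
#' Integer-pixel shift maximizing the normalized (Pearson) cross-correlation
#' over a bounded search window, with the correlation maximum as the quality
#' score. A zero-variance frame cannot be scored: it is flagged with score 0
#' and shift (0, 0).
#'
#' @param frame,reference_slice numeric matrices of identical size
#' @param max_shift search half-width in pixels
#' @return list with \code{shift} (dy, dx to apply to the frame),
#'   \code{score} in [-1, 1], and \code{flagged}
#' @export
register_slice <- function(frame, reference_slice, max_shift = 6L) {
  if (!all(dim(frame) == dim(reference_slice)))
    stop("frame and reference must have the same dimensions")
  cc <- ncc_surface(frame, reference_slice, max_shift)
  if (is.null(cc))
    return(list(shift = c(0L, 0L), score = 0, flagged = TRUE))
  i <- which.max(cc)                       # column-major: first max wins ties
  ar <- arrayInd(i, dim(cc))
  sh <- seq(-max_shift, max_shift)
  list(shift = c(sh[ar[1]], sh[ar[2]]), score = cc[i], flagged = FALSE)
}

#' Score and register every frame of a sequence against the reference
#'
#' @param frames \code{[y, x, z, repeat]} array or \code{repeat_stack_seq}
#' @param reference \code{[y, x, z]} reference (default: the initial average)
#' @param max_shift search half-width, px
#' @param channel channel selector for sequences
#' @return list with \code{scores} (\code{[repeat, z]} matrix) and
#'   \code{shifts} (\code{[2, repeat, z]} array)
#' @export
register_sequence <- function(frames, reference = NULL, max_shift = 6L,
                              channel = NULL) {
  frames <- get_channel_frames(frames, channel)
  if (is.null(reference)) reference <- build_reference_average(frames)
  d <- dim(frames)
  scores <- matrix(NA_real_, d[4], d[3])
  shifts <- array(0L, dim = c(2, d[4], d[3]))
  for (k in seq_len(d[3])) for (r in seq_len(d[4])) {
    reg <- register_slice(frames[, , k, r], reference[, , k], max_shift)
    scores[r, k] <- reg$score
    shifts[, r, k] <- reg$shift
  }
  list(scores = scores, shifts = shifts)
}

#' Reject motion-corrupted frames by the one-standard-deviation rule
#'
#' Per depth, the threshold is mean(score) - sd(score) with the sample (n-1)
#' standard deviation; a frame is kept iff its score is greater than or equal
#' to the threshold (the criterion discards frames strictly lower). A single
#' pass: the threshold is not recomputed after rejection.
#'
#' @param scores \code{[repeat, z]} matrix of correlation maxima
#' @return object of class \code{rejection_report}: \code{correlation},
#'   \code{mean}, \code{sd}, \code{threshold} (per depth), \code{kept}
#'   (\code{[repeat, z]} logical), \code{discard_fraction}
#' @export
reject_frames <- function(scores) {
  if (!is.matrix(scores)) scores <- matrix(scores, ncol = 1)
  if (nrow(scores) < 2) stop("need at least 2 scores per depth")
  mu <- colMeans(scores)
  sdv <- apply(scores, 2, stats::sd)
  thr <- mu - sdv
  # the criterion keeps scores at the threshold; the epsilon keeps that tie
  # rule stable when identical frames differ only in floating-point noise
  kept <- sweep(scores, 2, thr - 1e-9, `>=`)
  structure(list(correlation = scores, mean = mu, sd = sdv, threshold = thr,
                 kept = kept, discard_fraction = 1 - mean(kept)),
            class = "rejection_report")
}

#' Shift surviving frames into register and average them
#'
#' Surviving frames at each depth are translated by their registered integer
#' offset and averaged. Translation uncovers edge pixels; the output is
#' cropped to the common valid region across all surviving frames (never
#' zero-padded, so averages are not diluted).
#'
#' @param frames \code{[y, x, z, repeat]} array or \code{repeat_stack_seq}
#' @param report a \code{\link{reject_frames}} report
#' @param shifts \code{[2, repeat, z]} shift array from
#'   \code{\link{register_sequence}}
#' @param channel channel selector for sequences
#' @return object of class \code{registered_stack}: \code{volume}
#'   (\code{[y, x, z]} cropped average), \code{n_averaged} per depth,
#'   \code{crop} (row/col ranges kept), \code{shifts}
#' @export
assemble_final_stack <- function(frames, report, shifts, channel = NULL) {
  frames <- get_channel_frames(frames, channel)
  d <- dim(frames)
  kept <- report$kept
  if (!all(dim(kept) == d[c(4, 3)]))
    stop("report does not cover all frames")
  n_avg <- colSums(kept)
  if (any(n_avg == 0))
    stop(sprintf("no surviving frames at depth %s",
                 paste(which(n_avg == 0), collapse = ", ")))
  kept_idx <- which(kept, arr.ind = TRUE)      # (repeat, depth)
  dys <- shifts[1, , ][cbind(kept_idx[, 1], kept_idx[, 2])]
  dxs <- shifts[2, , ][cbind(kept_idx[, 1], kept_idx[, 2])]
  y0 <- 1L + max(0L, max(dys)); y1 <- d[1] + min(0L, min(dys))
  x0 <- 1L + max(0L, max(dxs)); x1 <- d[2] + min(0L, min(dxs))
  if (y0 > y1 || x0 > x1) stop("no common valid region after shifting")
  vol <- array(0, dim = c(y1 - y0 + 1L, x1 - x0 + 1L, d[3]))
  for (k in seq_len(d[3])) {
    acc <- matrix(0, y1 - y0 + 1L, x1 - x0 + 1L)
    for (r in which(kept[, k])) {
      sh <- shift_image(frames[, , k, r], shifts[1, r, k], shifts[2, r, k])
      acc <- acc + sh[y0:y1, x0:x1]
    }
    vol[, , k] <- acc / n_avg[k]
  }
  structure(list(volume = vol, n_averaged = n_avg,
                 crop = list(rows = c(y0, y1), cols = c(x0, x1)),
                 shifts = shifts),
            class = "registered_stack")
}

#' Register two z-stacks by 3D normalized cross-correlation
#'
#' Integer-voxel argmax of the zero-padded 3D Pearson cross-correlation;
#' returns the (dz, dy, dx) shift to apply to \code{stack_b} to align it with
#' \code{stack_a}. Used to co-register the final averaged NADH and FAD/keratin
#' excitation stacks.
#'
#' @param stack_a,stack_b \code{[y, x, z]} arrays of identical size
#' @param max_shift integer 3-vector of search half-widths (dz, dy, dx)
#' @return list with \code{shift} (dz, dy, dx) and \code{score}
#' @export
register_stacks_3d <- function(stack_a, stack_b, max_shift = c(2L, 6L, 6L)) {
  if (!all(dim(stack_a) == dim(stack_b)))
    stop("stacks must have the same dimensions")
  if (stats::sd(stack_a) == 0 || stats::sd(stack_b) == 0)
    stop("zero-variance stack cannot be registered")
  d <- dim(stack_a)
  ms <- as.integer(max_shift)                 # (dz, dy, dx)
  pd <- c(d[1] + 2L * ms[2], d[2] + 2L * ms[3], d[3] + 2L * ms[1])
  Ap <- array(0, pd); Bp <- array(0, pd)
  Ap[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- stack_a
  Bp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- stack_b
  cc <- Re(stats::fft(stats::fft(Bp) * Conj(stats::fft(Ap)), inverse = TRUE)) /
    prod(pd)   # circular index (u,v,w): sum b[y+u, x+v, z+w] * a[y, x, z]
  cum3 <- function(a) {
    a <- apply(a, c(2, 3), cumsum)
    a <- aperm(apply(a, c(1, 3), cumsum), c(2, 1, 3))
    out <- array(0, dim(a) + 1L)
    out[-1, -1, -1] <- aperm(apply(a, c(1, 2), cumsum), c(2, 3, 1))
    out
  }
  box3 <- function(I, r, c, z) {     # r, c, z are (lo, hi) index pairs
    I[r[2] + 1, c[2] + 1, z[2] + 1] - I[r[1], c[2] + 1, z[2] + 1] -
      I[r[2] + 1, c[1], z[2] + 1] - I[r[2] + 1, c[2] + 1, z[1]] +
      I[r[1], c[1], z[2] + 1] + I[r[1], c[2] + 1, z[1]] +
      I[r[2] + 1, c[1], z[1]] - I[r[1], c[1], z[1]]
  }
  Ia <- cum3(stack_a); Ia2 <- cum3(stack_a^2)
  Ib <- cum3(stack_b); Ib2 <- cum3(stack_b^2)
  shz <- seq(-ms[1], ms[1]); shy <- seq(-ms[2], ms[2]); shx <- seq(-ms[3], ms[3])
  best <- list(score = -Inf, shift = c(0L, 0L, 0L))
  for (dz in shz) for (dy in shy) for (dx in shx) {
    r <- c(1L + max(dy, 0L), d[1] + min(dy, 0L))
    cl <- c(1L + max(dx, 0L), d[2] + min(dx, 0L))
    zl <- c(1L + max(dz, 0L), d[3] + min(dz, 0L))
    n <- prod(r[2] - r[1] + 1, cl[2] - cl[1] + 1, zl[2] - zl[1] + 1)
    s_ab <- cc[((-dy) %% pd[1]) + 1L, ((-dx) %% pd[2]) + 1L,
               ((-dz) %% pd[3]) + 1L]
    s_b <- box3(Ib, r - dy, cl - dx, zl - dz)
    s_b2 <- box3(Ib2, r - dy, cl - dx, zl - dz)
    s_a <- box3(Ia, r, cl, zl)
    s_a2 <- box3(Ia2, r, cl, zl)
    vb <- s_b2 - s_b^2 / n; va <- s_a2 - s_a^2 / n
    sc <- if (vb <= 0 || va <= 0) 0 else (s_ab - s_a * s_b / n) / sqrt(va * vb)
    if (sc > best$score) best <- list(score = sc, shift = c(dz, dy, dx))
  }
  best[c("shift", "score")]
}
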