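# Small shared numerics used across the imaging modules.

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; depth-slice selection uses the
#' conventional half-up rule so that e.g. index 12.5 maps to 13.
#' @param x numeric
#' @return numeric vector of rounded values
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' Integer translation of an image with NA fill
#'
#' Content moves by \code{(dy, dx)} (positive = down/right); pixels shifted in
#' from outside the frame are \code{fill}.
#' @param img numeric matrix
#' @param dy,dx integer shifts in pixels
#' @param fill value for uncovered pixels
#' @return matrix of the same dimensions
#' @export
shift_image <- function(img, dy, dx, fill = NA_real_) {
  stopifnot(is.matrix(img))
  ny <- nrow(img); nx <- ncol(img)
  out <- matrix(fill, ny, nx)
  ys <- max(1L, 1L + dy):min(ny, ny + dy)
  xs <- max(1L, 1L + dx):min(nx, nx + dx)
  if (length(ys) > 0 && length(xs) > 0)
    out[ys, xs] <- img[ys - dy, xs - dx]
  out
}

#' Circular (content-preserving) translation
#' @inheritParams shift_image
#' @return matrix of the same dimensions
#' @export
circ_shift <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  dy <- ((dy %% ny) + ny) %% ny
  dx <- ((dx %% nx) + nx) %% nx
  idx_y <- c(seq_len(ny) - dy)
  idx_y <- ((idx_y - 1L) %% ny) + 1L
  idx_x <- c(seq_len(nx) - dx)
  idx_x <- ((idx_x - 1L) %% nx) + 1L
  img[idx_y, idx_x, drop = FALSE]
}

# Circular convolution of a vector with a kernel of equal length (FFT).
conv_circ <- function(x, k) {
  n <- length(x)
  stopifnot(length(k) == n)
  Re(stats::fft(stats::fft(x) * stats::fft(k), inverse = TRUE)) / n
}

# Neighborhood box sum over the spatial axes of [y, x] or [y, x, bin] arrays.
# Neighborhoods are truncated at the image border (each input pixel is counted
# at most once, so sums of independent Poisson pixels stay Poisson); a uniform
# input scales by (2*level+1)^2 away from the border.
box_sum <- function(arr, level) {
  stopifnot(level >= 0)
  if (level == 0) return(arr)
  d <- dim(arr)
  ny <- d[1]; nx <- d[2]
  acc <- array(0, dim = d)
  for (dy in -level:level) {
    ys <- max(1L, 1L + dy):min(ny, ny + dy)
    for (dx in -level:level) {
      xs <- max(1L, 1L + dx):min(nx, nx + dx)
      if (length(d) == 2L) {
        acc[ys, xs] <- acc[ys, xs] + arr[ys - dy, xs - dx, drop = FALSE]
      } else {
        acc[ys, xs, ] <- acc[ys, xs, ] + arr[ys - dy, xs - dx, , drop = FALSE]
      }
    }
  }
  acc
}

# Shoelace area of a closed polygon given as a two-column (x, y) matrix.
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}
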