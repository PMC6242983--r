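# Ki67/DAPI proliferation indexing of wound sections.

#' Otsu threshold of a traced region
#'
#' Threshold maximizing the between-class variance on a 256-bin histogram of
#' the region's pixel intensities. Deterministic; ties break toward the lower
#' threshold. Pixels strictly above the returned intensity are foreground.
#'
#' @param pixels numeric vector (or matrix) of region intensities with at
#'   least two distinct values
#' @param n_bins histogram resolution
#' @return threshold intensity (upper edge of the chosen background bin)
#' @export
otsu_threshold <- function(pixels, n_bins = 256L) {
  x <- as.numeric(pixels)
  mn <- min(x); mx <- max(x)
  if (mx <= mn) stop("constant region has no Otsu threshold")
  b <- pmin(floor((x - mn) / (mx - mn) * n_bins) + 1L, n_bins)
  cnt <- tabulate(b, nbins = n_bins)
  centers <- mn + (seq_len(n_bins) - 0.5) * (mx - mn) / n_bins
  w0 <- cumsum(cnt)[-n_bins]
  w1 <- length(x) - w0
  m0 <- cumsum(cnt * centers)[-n_bins]
  mu_tot <- sum(cnt * centers)
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (m0[valid] / w0[valid] - (mu_tot - m0[valid]) / w1[valid])^2 *
    w0[valid] * w1[valid]
  k <- which.max(bcv)            # which.max takes the first (lower) maximum
  mn + k * (mx - mn) / n_bins
}

# 8-connected component labeling by iterative minimum-label propagation: every
# foreground pixel starts with its own index and repeatedly takes the minimum
# over its 8-neighborhood until the labeling is stable (the minimum index
# floods each connected component).
label_components_8 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  fg <- mask != 0
  lab <- matrix(0, ny, nx)
  lab[fg] <- which(fg)
  if (!any(fg)) return(lab)
  repeat {
    m <- lab
    m[!fg] <- Inf
    best <- m
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      s <- matrix(Inf, ny, nx)
      ys <- max(1, 1 + dy):min(ny, ny + dy)
      xs <- max(1, 1 + dx):min(nx, nx + dx)
      s[ys, xs] <- m[ys - dy, xs - dx]
      best <- pmin(best, s)
    }
    best[!fg] <- 0
    if (all(best == lab)) break
    lab <- best
  }
  ids <- sort(unique(lab[lab > 0]))
  matrix(match(lab, c(0, ids), nomatch = 1L) - 1L, ny, nx)
}

#' Segment nuclei within a traced region
#'
#' Otsu-thresholds the channel within the region, labels 8-connected
#' components, and removes objects below the minimum area. Two nuclei joined
#' by even a single-pixel diagonal bridge merge into one component (a
#' documented consequence of 8-connectivity).
#'
#' An Otsu split of a unimodal region (a channel with no stained nuclei) is
#' meaningless — it would bisect the noise, and the suprathreshold pixels
#' percolate into spurious components. A contrast guard therefore requires
#' the class separation to exceed \code{min_contrast} pooled within-class
#' standard deviations; otherwise the mask is empty (zero components).
#'
#' @param channel intensity matrix
#' @param region logical matrix tracing the epithelial tongue; \code{NULL}
#'   uses the whole image
#' @param min_object_area smallest retained component, px
#' @param min_contrast minimum (mu_fg - mu_bg) / pooled within-class sd
#' @return object of class \code{nuclei_mask}: \code{mask}, \code{labels},
#'   \code{sizes}, \code{n}, \code{threshold}
#' @export
segment_nuclei <- function(channel, region = NULL, min_object_area = 20L,
                           min_contrast = 4) {
  if (is.null(region)) region <- matrix(TRUE, nrow(channel), ncol(channel))
  if (!any(region)) stop("empty traced region")
  thr <- otsu_threshold(channel[region])
  px <- channel[region]
  fg <- px > thr
  pooled_sd <- sqrt((sum((px[fg] - mean(px[fg]))^2) +
                       sum((px[!fg] - mean(px[!fg]))^2)) /
                      max(length(px) - 2, 1))
  if (!any(fg) || all(fg) ||
      (mean(px[fg]) - mean(px[!fg])) < min_contrast * pooled_sd) {
    lab <- matrix(0L, nrow(channel), ncol(channel))
    return(structure(list(mask = lab > 0L, labels = lab, sizes = integer(),
                          n = 0L, threshold = thr),
                     class = "nuclei_mask"))
  }
  bin <- channel > thr & region
  lab <- label_components_8(bin)
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < min_object_area)
  if (length(drop)) {
    lab[lab %in% drop] <- 0L
    keep <- which(sizes >= min_object_area)
    lab <- matrix(match(lab, c(0L, keep), nomatch = 1L) - 1L,
                  nrow(lab), ncol(lab))
    sizes <- sizes[keep]
  }
  structure(list(mask = lab > 0L, labels = lab, sizes = sizes,
                 n = length(sizes), threshold = thr),
            class = "nuclei_mask")
}

#' Ki67 proliferation index from overlaid nuclei masks
#'
#' A DAPI nucleus counts as Ki67-positive when at least \code{overlap_frac}
#' of its pixels fall inside the Ki67 mask (object-level co-localization; the
#' fractional criterion avoids single-pixel false positives). The index is
#' (Ki67 and DAPI co-localized nuclei) / (all DAPI nuclei).
#'
#' @param ki67,dapi \code{\link{segment_nuclei}} masks
#' @param overlap_frac minimum overlap fraction
#' @return object of class \code{proliferation_index}: \code{n_dapi},
#'   \code{n_coloc}, \code{index}
#' @export
proliferation_index <- function(ki67, dapi, overlap_frac = 0.25) {
  if (dapi$n == 0) stop("no DAPI nuclei")
  n_coloc <- 0L
  for (i in seq_len(dapi$n)) {
    px <- dapi$labels == i
    if (mean(ki67$mask[px]) >= overlap_frac) n_coloc <- n_coloc + 1L
  }
  structure(list(n_dapi = dapi$n, n_coloc = n_coloc,
                 index = n_coloc / dapi$n),
            class = "proliferation_index")
}

#' @export
print.proliferation_index <- function(x, ...) {
  cat(sprintf("proliferation index (Ki67 n DAPI)/DAPI: %d / %d = %.3f\n",
              x$n_coloc, x$n_dapi, x$index))
  invisible(x)
}
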