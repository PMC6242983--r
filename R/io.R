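# Multi-page TIFF exchange for image stacks (page order = depth ascending).

#' Write a z-stack as a multi-page 32-bit float TIFF
#'
#' TIFF float samples are stored in [0, 1]; intensities are divided by
#' \code{scale} on write, and the scale factor is returned so callers can
#' record it (the analysis drivers keep it in a sidecar JSON).
#'
#' @param volume \code{[y, x, z]} array of non-negative intensities
#' @param path output file
#' @param scale divisor applied before writing; defaults to the volume max
#' @return the scale factor, invisibly
#' @export
write_stack_tiff <- function(volume, path, scale = NULL) {
  stopifnot(length(dim(volume)) == 3)
  if (is.null(scale)) scale <- max(volume, 1)
  pages <- lapply(seq_len(dim(volume)[3]), function(k) volume[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(scale)
}

#' Read a multi-page TIFF as a z-stack array
#' @param path TIFF file
#' @param scale intensity scale recorded at write time
#' @return \code{[y, x, z]} array
#' @export
read_stack_tiff <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale * array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' Write a rejection report as CSV
#'
#' Long-format columns: repeat_idx, depth, score, threshold, kept.
#' @param report a \code{\link{reject_frames}} report
#' @param path output CSV
#' @return the data frame, invisibly
#' @export
write_rejection_csv <- function(report, path) {
  d <- dim(report$correlation)
  df <- data.frame(
    repeat_idx = rep(seq_len(d[1]), d[2]),
    depth = rep(seq_len(d[2]), each = d[1]),
    score = as.vector(report$correlation),
    threshold = rep(report$threshold, each = d[1]),
    kept = as.vector(report$kept))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
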