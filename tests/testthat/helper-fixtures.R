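# Shared fixtures and independent oracles, built in code at test time.

# Small wound-edge volume + config used by several suites.
small_config <- function(...) {
  acq_config(image_size = c(48L, 48L), z_depth = 20, n_repeats = 10L, ...)
}

# Brute-force windowed-Pearson registration: direct loops over every shift,
# Pearson correlation computed on the overlap region from first principles.
brute_force_register <- function(frame, ref, max_shift) {
  best <- -Inf; bs <- c(0L, 0L)
  ny <- nrow(frame); nx <- ncol(frame)
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    a <- frame[ys - dy, xs - dx]
    b <- ref[ys, xs]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    v <- stats::cor(as.vector(a), as.vector(b))
    if (v > best) { best <- v; bs <- c(dy, dx) }
  }
  list(shift = bs, score = best)
}

# Exhaustive Otsu: loop over all candidate thresholds, between-class variance
# computed naively from the binned class means.
otsu_oracle <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  mn <- min(x); mx <- max(x)
  b <- pmin(floor((x - mn) / (mx - mn) * n_bins) + 1L, n_bins)
  centers <- mn + (seq_len(n_bins) - 0.5) * (mx - mn) / n_bins
  v <- centers[b]
  best <- -Inf; bk <- 1L
  for (k in seq_len(n_bins - 1L)) {
    lo <- b <= k
    n0 <- sum(lo); n1 <- sum(!lo)
    if (n0 == 0 || n1 == 0) next
    bcv <- n0 * n1 * (mean(v[lo]) - mean(v[!lo]))^2
    if (bcv > best) { best <- bcv; bk <- k }
  }
  mn + bk * (mx - mn) / n_bins
}

# Expected (noiseless) decay histogram: incomplete bi-exponential at the bin
# centers, circularly convolved with the IRF, scaled to `counts` photons.
expected_decay <- function(A1, tau1, A2, tau2, irf, config, counts) {
  nb <- config$tcspc_bins
  tc <- (seq_len(nb) - 0.5) * config$tcspc_bin_width_ps / 1000
  m <- incomplete_biexp_model(tc, config$laser_period_ns, A1, tau1, A2, tau2)
  mc <- pmax(Re(stats::fft(stats::fft(m) * stats::fft(irf),
                           inverse = TRUE)) / nb, 0)
  mc / sum(mc) * counts
}
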