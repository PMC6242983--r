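# Incomplete bi-exponential model, decay fitting, binning, phasors.

test_that("incomplete decay model has its closed-form values and integral", {
  # periodic pile-up factor at t = 0 for the long component
  expect_equal(incomplete_biexp_model(0, 12.5, 1, 3679),
               1 / (1 - exp(-12.5 / 3.679)), tolerance = 1e-12)
  # short lifetimes reduce to the plain exponential
  t <- seq(0, 12.4, by = 0.1)
  expect_lt(max(abs(incomplete_biexp_model(t, 12.5, 1, 100) -
                      exp(-t / 0.1))), 1e-50)
  # analytic integral over one period equals sum A_k tau_k
  f <- function(t) incomplete_biexp_model(t, 12.5, 2, 536, 3, 3679)
  got <- stats::integrate(f, 0, 12.5, rel.tol = 1e-10)$value
  expect_equal(got, 2 * 0.536 + 3 * 3.679, tolerance = 1e-8)
  expect_error(incomplete_biexp_model(0, 12.5, 1, -5), "tau")
})

test_that("spatial binning sums square neighborhoods to the photon target", {
  cfg <- acq_config()
  irf <- generate_irf(0.25, cfg$tcspc_bin_width_ps, cfg$tcspc_bins)
  img <- generate_flim_image(list(A1 = 1, tau1_ps = 536, A2 = 1,
                                  tau2_ps = 3679), irf, cfg,
                             counts_target = 400, image_size = c(16L, 16L),
                             seed = NULL)
  sb <- spatial_bin(img, target_counts = 10000, max_bin = 2)
  expect_equal(sb$level, 2L)
  expect_true(sb$reached)
  # interior of a uniform image scales by (2*2+1)^2 = 25
  expect_equal(sb$image$histograms[8, 8, ], 25 * img$histograms[8, 8, ])
  expect_equal(sum(sb$image$histograms[8, 8, ]), 10000)
  # level 0 is the identity
  sb0 <- spatial_bin(img, target_counts = 100, max_bin = 2)
  expect_equal(sb0$level, 0L)
  expect_identical(sb0$image$histograms, img$histograms)
  # unreachable target warns and flags
  expect_warning(sb_far <- spatial_bin(img, target_counts = 1e7, max_bin = 2),
                 "below target")
  expect_false(sb_far$reached)
})

test_that("decay fitting recovers noiseless parameters to 0.1 percent", {
  cfg <- acq_config()
  irf <- generate_irf(0.25, cfg$tcspc_bin_width_ps, cfg$tcspc_bins)
  h <- expected_decay(1, 536, 1, 3679, irf, cfg, 1e7)
  f <- fit_decay(h, irf, cfg$laser_period_ns, cfg$tcspc_bin_width_ps)
  expect_lt(abs(f$tau1 / 536 - 1), 1e-3)
  expect_lt(abs(f$tau2 / 3679 - 1), 1e-3)
  expect_lt(abs(f$A1 / f$A2 - 1), 1e-3)
  expect_lt(f$chi2, 1e-6)
  expect_true(f$accepted)
  # noiseless mono-exponential collapses to one component
  hm <- expected_decay(1, 2000, 0, Inf, irf, cfg, 1e7)
  fm <- fit_decay(hm, irf, cfg$laser_period_ns, cfg$tcspc_bin_width_ps)
  expect_lt(abs(fm$tau1 - 2000), 1)
  expect_lt(fm$chi2, 1e-6)
  expect_lt(fm$A2 / fm$A1, 0.05)
  expect_error(fit_decay(rep(0, cfg$tcspc_bins), irf, 12.5), "no counts")
})

test_that("reduced chi-square is calibrated on correctly specified data", {
  cfg <- acq_config()
  irf <- generate_irf(0.25, cfg$tcspc_bin_width_ps, cfg$tcspc_bins)
  p <- expected_decay(1, 536, 1, 3679, irf, cfg, 1e4)
  set.seed(31)
  chi <- replicate(120, {
    f <- fit_decay(rpois(cfg$tcspc_bins, p), irf, cfg$laser_period_ns,
                   cfg$tcspc_bin_width_ps)
    c(f$chi2, f$accepted)
  })
  expect_gt(mean(chi[1, ]), 0.9)
  expect_lt(mean(chi[1, ]), 1.1)
  expect_gte(mean(chi[2, ]), 0.95)     # acceptance rate under chi2 < 1.5
})

test_that("lifetime recovery at the study photon budget is nearly unbiased", {
  cfg <- acq_config()
  irf <- generate_irf(0.25, cfg$tcspc_bin_width_ps, cfg$tcspc_bins)
  p <- expected_decay(1, 536, 1, 3679, irf, cfg, 1e4)
  set.seed(77)
  fits <- do.call(rbind, lapply(1:60, function(i)
    fit_decay(rpois(cfg$tcspc_bins, p), irf, cfg$laser_period_ns,
              cfg$tcspc_bin_width_ps)))
  acc <- fits[fits$accepted, ]
  expect_lt(abs(mean(acc$tau1) / 536 - 1), 0.05)
  expect_lt(abs(mean(acc$tau2) / 3679 - 1), 0.05)
})

test_that("epithelial A1/A2 averages per-pixel ratios over accepted pixels", {
  fits <- data.frame(y = c(1, 1, 2), x = c(1, 2, 1),
                     A1 = c(1, 3, 8), A2 = c(1, 1, 1),
                     chi2 = c(0.9, 1.0, 2.5),
                     accepted = c(TRUE, TRUE, FALSE))
  # mean of ratios (1 and 3), not ratio of sums; rejected pixel excluded
  expect_equal(epithelial_a1a2(fits), 2)
  msk <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(epithelial_a1a2(fits, msk), 1)
  fits$accepted <- FALSE
  expect_error(epithelial_a1a2(fits), "no accepted")
})

test_that("A1/A2 ratio is recovered from the binned study-condition fixture", {
  cfg <- acq_config()
  irf <- generate_irf(0.25, cfg$tcspc_bin_width_ps, cfg$tcspc_bins)
  p <- expected_decay(1.5, 536, 1, 3679, irf, cfg, 1e4)
  set.seed(19)
  fits <- do.call(rbind, lapply(1:400, function(i) {
    f <- fit_decay(rpois(cfg$tcspc_bins, p), irf, cfg$laser_period_ns,
                   cfg$tcspc_bin_width_ps)
    cbind(data.frame(y = i, x = 1L), f)
  }))
  expect_lt(abs(epithelial_a1a2(fits) - 1.5), 0.05)
})

test_that("phasor transform obeys the mono-exponential closed forms", {
  nb <- 256L
  cfg <- acq_config(tcspc_bins = nb)
  bw <- cfg$tcspc_bin_width_ps
  tc <- (seq_len(nb) - 0.5) * bw / 1000
  w <- 2 * pi * 80e-3
  # tau = 1/omega sits at (1/2, 1/2)
  h <- incomplete_biexp_model(tc, 12.5, 1, 1000 / w)
  ph <- phasor_transform(h, NULL, 80, bw)
  expect_equal(c(ph$g, ph$s), c(0.5, 0.5), tolerance = 1e-3)
  # limits: tau -> 0 tends to (1, 0) at the resolution of the bin grid
  # (a delta in the first bin carries the half-bin phase w * bw / 2)
  h0 <- incomplete_biexp_model(tc, 12.5, 1, 1)
  p0 <- phasor_transform(h0, NULL, 80, bw)
  expect_equal(p0$g, 1, tolerance = 1e-3)
  expect_equal(p0$s, 0, tolerance = w * bw / 2000 * 1.1)
  # tau -> Inf gives (0, 0)
  hi <- incomplete_biexp_model(tc, 12.5, 1, 1e7)
  pi_ <- phasor_transform(hi, NULL, 80, bw)
  expect_equal(c(pi_$g, pi_$s), c(0, 0), tolerance = 5e-3)
  # any mono-exponential lands on the universal semicircle after deconvolution
  irf <- generate_irf(0.25, bw, nb)
  for (tau in c(300, 536, 1500, 3679, 6000)) {
    hc <- expected_decay(1, tau, 0, Inf, irf, cfg, 1e6)
    p <- phasor_transform(hc, irf, 80, bw)
    expect_lt(abs((p$g - 0.5)^2 + p$s^2 - 0.25), 1e-3)
  }
  expect_error(phasor_transform(rep(0, nb), NULL, 80, bw), "no counts")
})

test_that("two-species mixtures stay on the chord, other species leave it", {
  nb <- 64L
  cfg <- acq_config(tcspc_bins = nb)
  bw <- cfg$tcspc_bin_width_ps
  irf <- generate_irf(0.25, bw, nb)
  pts <- do.call(rbind, lapply(c(0, 0.25, 0.5, 0.75, 1), function(fr) {
    h <- expected_decay(fr, 536, 1 - fr, 3679, irf, cfg, 1e6)
    p <- phasor_transform(h, irf, 80, bw)
    data.frame(g = p$g, s = p$s)
  }))
  chk <- two_species_check(pts, 536, 3679, 12.5, bw, nb)
  expect_lt(chk$max_distance, 1e-6)
  # single pure species sits at an endpoint: distance 0
  chk1 <- two_species_check(pts[1, ], 536, 3679, 12.5, bw, nb)
  expect_lt(chk1$max_distance, 1e-9)
  # a third lifetime falls off the chord
  h3 <- expected_decay(1, 1500, 0, Inf, irf, cfg, 1e6)
  p3 <- phasor_transform(h3, irf, 80, bw)
  chk3 <- two_species_check(data.frame(g = p3$g, s = p3$s), 536, 3679,
                            12.5, bw, nb)
  expect_gt(chk3$max_distance, 0.01)
  expect_error(two_species_check(pts, 1000, 1000, 12.5, bw, nb), "degenerate")
})

test_that("fitted parameters reconstruct the pixel's deconvolved phasor", {
  cfg <- acq_config()
  bw <- cfg$tcspc_bin_width_ps
  irf <- generate_irf(0.25, bw, cfg$tcspc_bins)
  p <- expected_decay(1.2, 536, 1, 3679, irf, cfg, 2e4)
  set.seed(55)
  h <- rpois(cfg$tcspc_bins, p)
  f <- fit_decay(h, irf, cfg$laser_period_ns, bw)
  obs <- phasor_transform(h, irf, 80, bw)
  tc <- (seq_len(cfg$tcspc_bins) - 0.5) * bw / 1000
  recon <- phasor_transform(
    incomplete_biexp_model(tc, 12.5, f$A1, f$tau1, f$A2, f$tau2), NULL, 80, bw)
  expect_lt(sqrt((obs$g - recon$g)^2 + (obs$s - recon$s)^2), 0.02)
})
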