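# Generators: geometry, ground-truth consistency, seed determinism.

test_that("acquisition config validates its geometry", {
  expect_error(acq_config(n_repeats = 1), "n_repeats")
  expect_error(acq_config(z_depth = 7, z_step = 5), "multiple")
  expect_error(acq_config(laser_period_ns = 0), "laser_period")
  cfg <- acq_config(z_depth = 250, z_step = 5)
  expect_equal(cfg$n_slices, 51L)
})

test_that("noiseless wound volume reproduces its true redox field exactly", {
  cfg <- small_config()
  vol <- generate_wound_edge_volume(cfg)
  ratio <- vol$channels$FAD / (vol$channels$NADH + vol$channels$FAD)
  expect_lt(max(abs(ratio - vol$truth$true_redox_field)), 1e-12)
  expect_true(all(vol$truth$true_redox_field >= 0 &
                    vol$truth$true_redox_field <= 1))
  # uniform redox 0.5 forces channel equality within the epithelium
  sc <- wound_scene_params(redox_base = 0.5, redox_tip = 0.5)
  v2 <- generate_wound_edge_volume(cfg, sc)
  m <- v2$truth$epithelial_mask
  expect_equal(v2$channels$NADH[m], v2$channels$FAD[m])
  # all-NADH scene: zero FAD means redox identically 0
  sc0 <- wound_scene_params(redox_base = 0, redox_tip = 0,
                            dermis_redox = 0, wound_redox = 0)
  v0 <- generate_wound_edge_volume(cfg, sc0)
  expect_true(all(v0$channels$FAD == 0))
  expect_true(all(v0$truth$true_redox_field[v0$truth$epithelial_mask] == 0))
  # linear gradient reproduced per pixel
  scl <- wound_scene_params(redox_profile = "linear")
  vl <- generate_wound_edge_volume(cfg, scl)
  u <- vl$truth$tongue_u[vl$truth$tongue_mask]
  r <- (vl$channels$FAD / (vl$channels$NADH + vl$channels$FAD))[
    vl$truth$tongue_mask]
  expect_lt(max(abs(r - (0.35 + 0.25 * u))), 1e-12)
  expect_error(generate_wound_edge_volume(
    cfg, wound_scene_params(edge_frac = 0.9, tip_frac = 0.2)), "degenerate")
})

test_that("tongue region thirds carry the gradient endpoints", {
  vol <- generate_wound_edge_volume(small_config())
  rg <- tongue_region_masks(vol$truth)
  expect_equal(mean(vol$truth$true_redox_field[rg$basal]), 0.35)
  expect_equal(mean(vol$truth$true_redox_field[rg$distal]), 0.6)
})

test_that("motion artifacts follow the seeded corruption protocol", {
  cfg <- small_config()
  vol <- generate_wound_edge_volume(cfg)
  expect_error(inject_motion_artifacts(vol, cfg, artifact_prob = 1), "artifact_prob")
  s0 <- inject_motion_artifacts(vol$channels$NADH, cfg, artifact_prob = 0, seed = 3)
  expect_equal(nrow(s0$artifact_frames), 0L)
  # seeded binomial count is recomputable from the documented protocol
  cfg50 <- acq_config(image_size = c(32L, 32L), z_depth = 0, n_repeats = 50L)
  v1 <- generate_wound_edge_volume(cfg50)
  s1 <- inject_motion_artifacts(v1$channels$NADH, cfg50, artifact_prob = 0.08,
                                seed = 11)
  set.seed(11)
  expected_n <- sum(stats::runif(50 * 1) < 0.08)
  expect_equal(nrow(s1$artifact_frames), expected_n)
  # bit-identical under the same seed
  s2 <- inject_motion_artifacts(v1$channels$NADH, cfg50, artifact_prob = 0.08,
                                seed = 11)
  expect_identical(s1$channels, s2$channels)
  expect_identical(s1$artifact_frames, s2$artifact_frames)
  # small jitter never exceeds 2 px
  expect_true(all(abs(s1$jitter) <= 2))
})

test_that("generated IRF is normalized with the requested width", {
  irf <- generate_irf(0.25, bin_width_ps = 10, n_bins = 1250)
  expect_equal(sum(irf), 1)
  expect_lt(abs(measure_fwhm(irf, 10) - 0.25), 0.01)
  # sigma of the analytic Gaussian follows FWHM = 2 sqrt(2 log 2) sigma
  irf2 <- generate_irf(0.5, bin_width_ps = 5, n_bins = 2500, center_ns = 3)
  tc <- (seq_along(irf2) - 0.5) * 5 / 1000
  sigma_hat <- sqrt(sum(irf2 * (tc - sum(irf2 * tc))^2))
  expect_lt(abs(sigma_hat - 0.5 / (2 * sqrt(2 * log(2)))), 1e-3)
  expect_error(generate_irf(0.005, bin_width_ps = 10), "bin width")
  expect_error(generate_irf(-1), "positive")
})

test_that("decay image generator matches its analytic expectation", {
  cfg <- acq_config()
  irf <- generate_irf(0.25, cfg$tcspc_bin_width_ps, cfg$tcspc_bins)
  tl <- list(A1 = 1, tau1_ps = 536, A2 = 1, tau2_ps = 3679)
  img <- generate_flim_image(tl, irf, cfg, counts_target = 5000,
                             image_size = c(2, 2), seed = NULL)
  # noiseless histogram integrates to the photon target
  expect_equal(sum(img$histograms[1, 1, ]), 5000)
  # its deconvolved phasor equals the closed-form two-species mixture phasor
  p <- phasor_transform(img$histograms[1, 1, ], irf, 80, cfg$tcspc_bin_width_ps)
  pure <- function(tau) {
    h <- expected_decay(1, tau, 0, Inf, irf, cfg, 1)
    ph <- phasor_transform(h, irf, 80, cfg$tcspc_bin_width_ps)
    complex(real = ph$g, imaginary = ph$s)
  }
  tc <- (seq_len(cfg$tcspc_bins) - 0.5) * cfg$tcspc_bin_width_ps / 1000
  s1 <- sum(incomplete_biexp_model(tc, 12.5, 1, 536))
  s2 <- sum(incomplete_biexp_model(tc, 12.5, 1, 3679))
  w1 <- s1 / (s1 + s2)                          # photon-weighted mixture
  zmix <- w1 * pure(536) + (1 - w1) * pure(3679)
  expect_lt(Mod(complex(real = p$g, imaginary = p$s) - zmix), 1e-6)
  # doubling the target doubles expected counts; linearity of the model
  img2 <- generate_flim_image(tl, irf, cfg, counts_target = 10000,
                              image_size = c(2, 2), seed = NULL)
  expect_equal(img2$histograms[1, 1, ], 2 * img$histograms[1, 1, ])
  # equal amplitudes mean true A1/A2 of 1 by construction
  expect_equal(tl$A1 / tl$A2, 1)
  # determinism of the Poisson draw
  a <- generate_flim_image(tl, irf, cfg, 400, c(4, 4), seed = 9)
  b <- generate_flim_image(tl, irf, cfg, 400, c(4, 4), seed = 9)
  expect_identical(a$histograms, b$histograms)
})

test_that("histology generator places the exact Ki67-positive count", {
  h <- generate_histology_image(10, 0.4, seed = 2)
  expect_equal(sum(h$truth$ki67_positive), 4L)
  h0 <- generate_histology_image(12, 0, seed = 2)
  expect_equal(sum(h0$truth$ki67_positive), 0L)
  # background-only Ki67 channel: no blob exceeds background + noise
  expect_lt(max(h0$ki67), 0.05 + 6 * 0.02)
  h1 <- generate_histology_image(12, 1, seed = 2)
  ctr <- round(h1$truth$centers)
  expect_true(all(h1$ki67[ctr] > 0.5))
  expect_error(generate_histology_image(500, 0.5, image_size = c(64, 64),
                                        seed = 1), "overcrowded")
})

test_that("calibration series follows the power-law gain model", {
  s <- generate_calibration_series(prefactor = 2, exponent = 6,
                                   voltages = c(1, 2), concentrations = c(1),
                                   laser_power = 1, noise_cv = 0)
  expect_equal(s$intensity[s$pmt_voltage == 2] /
                 s$intensity[s$pmt_voltage == 1], 64)
  s2 <- generate_calibration_series(noise_cv = 0,
                                    concentrations = c(0.5, 1, 2, 4),
                                    voltages = 700)
  expect_equal(diff(diff(s2$intensity / s2$concentration)), c(0, 0))
  # study range of fluorescein standards
  s3 <- generate_calibration_series(noise_cv = 0)
  expect_equal(range(s3$concentration), c(0.1, 20))
  expect_true(all(diff(s3$intensity[s3$pmt_voltage == 700]) > 0))
  expect_error(generate_calibration_series(noise_cv = -0.1), "noise_cv")
})

test_that("wound tracings reproduce the closure curve within 1 percent", {
  curve <- c(1, 0.9, 0.7, 0.5, 0.35, 0.22)
  tr <- generate_wound_tracings(curve, seed = 8)
  cl <- closure_from_tracings(tr)
  expect_equal(cl$relative_area[1], 1)
  expect_lt(max(abs(cl$relative_area - curve)), 0.01)
  # 6 mm punch: day-0 area close to the circle area pi * 3^2
  expect_lt(abs(tr$areas_mm2[1] - pi * 9) / (pi * 9), 0.01)
  expect_error(generate_wound_tracings(c(1, 1.2), days = c(0, 3)), "\\(0, 1]")
  expect_error(generate_wound_tracings(c(0.9, 0.5), days = c(0, 3)), "day 0")
})
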