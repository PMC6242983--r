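# Frame scoring, rejection rule, registration and averaging.

test_that("reference average is the unweighted per-depth mean", {
  cfg <- acq_config(image_size = c(16L, 16L), z_depth = 10, n_repeats = 2L)
  fr <- array(0, dim = c(16, 16, 3, 2))
  fr[, , , 1] <- 10; fr[, , , 2] <- 20
  expect_equal(build_reference_average(fr), array(15, dim = c(16, 16, 3)))
  # identical repeats: reference equals either one
  set.seed(1)
  a <- array(rnorm(16 * 16 * 3), dim = c(16, 16, 3))
  fr2 <- array(a, dim = c(16, 16, 3, 2))
  expect_equal(build_reference_average(fr2), a)
  expect_error(build_reference_average(array(0, c(4, 4, 2, 1))), "2 repeats")
})

test_that("averaging reduces noise variance like 1/n", {
  set.seed(42)
  scene <- matrix(rnorm(48 * 48, 100, 20), 48)
  n_rep <- 10L
  fr <- array(0, dim = c(48, 48, 1, n_rep))
  for (r in seq_len(n_rep)) fr[, , 1, r] <- scene + rnorm(48 * 48, 0, 10)
  ref <- build_reference_average(fr)
  v1 <- mean((fr[, , 1, 1] - scene)^2)
  vm <- mean((ref[, , 1] - scene)^2)
  expect_lt(abs(vm / (v1 / n_rep) - 1), 0.35)
})

test_that("slice registration equals brute force and recovers shifts exactly", {
  vol <- generate_wound_edge_volume(small_config())
  ref <- vol$channels$NADH[, , 1]
  # exact recovery with unit score for content-preserving shifts
  for (s in list(c(3, -2), c(0, 0), c(-5, 5), c(1, 4))) {
    reg <- register_slice(circ_shift(ref, s[1], s[2]), ref)
    expect_equal(reg$shift, -s)
    expect_equal(reg$score, 1, tolerance = 1e-9)
  }
  # oracle equivalence on small noisy images, several seeds
  for (seed in 1:4) {
    set.seed(seed)
    r0 <- matrix(rnorm(32 * 32), 32)
    f0 <- circ_shift(r0, sample(-4:4, 1), sample(-4:4, 1)) +
      matrix(rnorm(32 * 32, 0, 0.4), 32)
    got <- register_slice(f0, r0, max_shift = 4L)
    bf <- brute_force_register(f0, r0, max_shift = 4L)
    expect_equal(got$shift, bf$shift)
    expect_equal(got$score, bf$score, tolerance = 1e-9)
  }
  # constant frame is flagged, not scored
  flat <- register_slice(matrix(5, 32, 32), ref[1:32, 1:32])
  expect_true(flat$flagged)
  expect_equal(flat$score, 0)
  expect_equal(flat$shift, c(0L, 0L))
  expect_error(register_slice(matrix(0, 3, 3), matrix(0, 4, 4)), "dimensions")
})

test_that("rejection applies the mean minus one sample-sd rule per depth", {
  rep1 <- reject_frames(matrix(c(0.9, 0.9, 0.9, 0.3), ncol = 1))
  expect_equal(rep1$mean, 0.75)
  expect_equal(rep1$sd, 0.3)
  expect_equal(rep1$threshold, 0.45)
  expect_equal(as.vector(rep1$kept), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(rep1$discard_fraction, 0.25)
  # equal scores: sd 0, threshold = mean, everything kept (score >= threshold)
  rep2 <- reject_frames(matrix(0.8, 5, 2))
  expect_true(all(rep2$kept))
  expect_equal(rep2$discard_fraction, 0)
  expect_error(reject_frames(matrix(1, 1, 3)), "2 scores")
  # lowering a score never un-rejects a frame (single-pass monotonicity)
  sc <- matrix(c(0.95, 0.9, 0.92, 0.91, 0.2, 0.94), ncol = 1)
  base <- reject_frames(sc)
  sc2 <- sc; sc2[5] <- 0.05
  again <- reject_frames(sc2)
  expect_true(all(again$kept[!base$kept] == FALSE))
})

test_that("corrupted frames are rejected with full recall on the seeded fixture", {
  cfg <- acq_config(image_size = c(48L, 48L), z_depth = 20, n_repeats = 50L)
  vol <- generate_wound_edge_volume(cfg)
  seqn <- inject_motion_artifacts(vol$channels$NADH, cfg, artifact_prob = 0.08,
                                  seed = 7)
  reg <- register_sequence(seqn)
  rep_ <- reject_frames(reg$scores)
  art <- matrix(FALSE, cfg$n_repeats, cfg$n_slices)
  art[cbind(seqn$artifact_frames$repeat_idx, seqn$artifact_frames$depth)] <- TRUE
  expect_gt(sum(art), 5)
  expect_equal(mean(!rep_$kept[art]), 1)          # recall
  expect_lte(mean(!rep_$kept[!art]), 0.05)        # false rejection
})

test_that("final stack averaging conserves intensity over the common region", {
  cfg <- acq_config(image_size = c(32L, 32L), z_depth = 10, n_repeats = 4L)
  vol <- generate_wound_edge_volume(cfg)
  nz <- cfg$n_slices
  # survivors are copies of the scene under known shifts
  shifts_true <- cbind(c(0, 2, -1, 1), c(0, -2, 1, 0))
  fr <- array(0, dim = c(32, 32, nz, 4))
  for (r in 1:4) for (k in seq_len(nz))
    fr[, , k, r] <- circ_shift(vol$channels$NADH[, , k],
                               shifts_true[r, 1], shifts_true[r, 2])
  reg <- register_sequence(fr, reference = vol$channels$NADH)
  expect_true(all(reg$shifts[1, , ] == -shifts_true[, 1]))
  expect_true(all(reg$shifts[2, , ] == -shifts_true[, 2]))
  rep_ <- reject_frames(reg$scores)
  fs <- assemble_final_stack(fr, rep_, reg$shifts)
  rows <- fs$crop$rows; cols <- fs$crop$cols
  truth <- vol$channels$NADH[rows[1]:rows[2], cols[1]:cols[2], ]
  expect_lt(max(abs(fs$volume - truth)), 1e-9)
  expect_equal(fs$n_averaged, rep(4L, nz))
  # with no rejections and zero shifts the final stack is the plain average
  fr0 <- fr
  for (r in 1:4) for (k in seq_len(nz)) fr0[, , k, r] <- vol$channels$NADH[, , k]
  reg0 <- register_sequence(fr0)
  fs0 <- assemble_final_stack(fr0, reject_frames(reg0$scores), reg0$shifts)
  expect_equal(fs0$volume, build_reference_average(fr0))
  # zero survivors at a depth is an error naming the depth
  bad <- reject_frames(matrix(c(0.9, 0.9, 0.9, 0.3), ncol = 1))
  bad$kept[] <- FALSE
  expect_error(assemble_final_stack(array(1, c(8, 8, 1, 4)), bad,
                                    array(0L, c(2, 4, 1))), "depth 1")
})

test_that("averaging improves SNR by roughly sqrt(n)", {
  cfg <- acq_config(image_size = c(48L, 48L), z_depth = 0, n_repeats = 10L)
  vol <- generate_wound_edge_volume(cfg)
  seqn <- inject_motion_artifacts(vol$channels$NADH, cfg, artifact_prob = 0,
                                  jitter_px = 0L, seed = 5)
  reg <- register_sequence(seqn)
  rep_ <- reject_frames(reg$scores)
  fs <- assemble_final_stack(seqn, rep_, reg$shifts)
  truth <- vol$channels$NADH[fs$crop$rows[1]:fs$crop$rows[2],
                             fs$crop$cols[1]:fs$crop$cols[2], 1]
  snr <- function(x) sd(truth) / sqrt(mean((x - truth)^2))
  frame1 <- seqn$channels[[1]][fs$crop$rows[1]:fs$crop$rows[2],
                               fs$crop$cols[1]:fs$crop$cols[2], 1, 1]
  n_eff <- fs$n_averaged[1]
  expect_gte(snr(fs$volume[, , 1]), 0.8 * sqrt(n_eff) * snr(frame1))
})

test_that("3D registration recovers integer voxel offsets", {
  vol <- generate_wound_edge_volume(small_config())
  a <- vol$channels$NADH
  expect_equal(register_stacks_3d(a, a)$shift, c(0L, 0L, 0L))
  b <- a[, , c(dim(a)[3], seq_len(dim(a)[3] - 1L))]     # +1 z displacement
  b <- array(apply(b, 3, function(m) circ_shift(m, 4, -3)), dim(a))
  r3 <- register_stacks_3d(a, b)
  expect_equal(r3$shift, c(-1, -4, 3))
  # co-registered noiseless channels sit at zero offset
  r0 <- register_stacks_3d(vol$channels$NADH, vol$channels$FAD)
  expect_equal(r0$shift, c(0L, 0L, 0L))
  expect_error(register_stacks_3d(array(1, c(4, 4, 2)), array(1, c(4, 4, 2))),
               "zero-variance")
})
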