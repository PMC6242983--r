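#!/usr/bin/env Rscript
# Simulate one wound-edge location: the noiseless three-channel scene and the
# repeated, motion-corrupted acquisition sequence. Writes the per-channel
# repeat stacks as multi-page TIFFs plus a sidecar JSON with the acquisition
# configuration and ground truth bookkeeping.

library(mpmwound)
library(jsonlite)

out_dir <- "results/01_stacks"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- acq_config(seed = 42L)          # reduced geometry: 128x128, 11 z, 10 repeats
scene <- wound_scene_params()
vol <- generate_wound_edge_volume(cfg, scene)
seqn <- inject_motion_artifacts(vol, cfg, artifact_prob = 0.08, seed = 42L)

scales <- list()
for (ch in names(seqn$channels)) {
  for (r in seq_len(cfg$n_repeats)) {
    f <- file.path(out_dir, sprintf("%s_rep%02d.tif", ch, r))
    scales[[sprintf("%s_rep%02d", ch, r)]] <-
      write_stack_tiff(seqn$channels[[ch]][, , , r], f)
  }
}

write_json(list(
  config = unclass(cfg),
  scene = scene,
  artifact_frames = seqn$artifact_frames,
  tiff_scales = scales,
  seed = 42L
), file.path(out_dir, "acquisition.json"), auto_unbox = TRUE, digits = NA)

n_art <- nrow(seqn$artifact_frames)
message(sprintf("simulated %d x %d x %d stack, %d repeats/channel; %d of %d frames carry motion artifacts (%.1f%%)",
                cfg$image_size[1], cfg$image_size[2], cfg$n_slices,
                cfg$n_repeats, n_art, cfg$n_repeats * cfg$n_slices,
                100 * n_art / (cfg$n_repeats * cfg$n_slices)))
message("wrote ", out_dir)
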