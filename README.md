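# mpmwound

Label-free multiphoton microscopy can monitor the metabolism of a healing
skin wound in a living animal: NADH fluoresces when reduced, FAD when
oxidized, so the optical redox ratio **FAD/(NADH+FAD)** of their
autofluorescence tracks the balance between glycolysis/biosynthesis and
oxidative metabolism in wound-edge keratinocytes, and the NADH fluorescence
lifetime separates free (short component, amplitude A1) from protein-bound
(long component, A2) NADH. `mpmwound` implements the full analysis chain such
a longitudinal experiment needs, for image analysts working with repeated in
vivo two-photon z-stacks of wounds in diabetic and control mice:

- **Synthetic acquisition generator** — every input the pipeline consumes,
  with known ground truth: repeated three-channel z-stacks (NADH 755/460 nm,
  FAD+keratin 900/525 nm, collagen SHG 900/460 nm) with Poisson/read noise
  and stochastic motion-corrupted frames; per-pixel TCSPC decay histograms
  under 80 MHz excitation convolved with a 0.25 ns FWHM Gaussian IRF;
  fluorescein calibration series; Ki67/DAPI nuclei images; digitized wound
  tracings.
- **Motion correction** — per-depth averaging of the repeat sequence,
  frame scoring by windowed-Pearson cross-correlation against the average,
  rejection of frames scoring below mean − 1 sd per depth, re-registration
  and averaging of survivors, 3D co-registration of the excitation channels.
- **Calibration and redox mapping** — power-law PMT gain calibration from
  fluorescein standards (intensity ∝ concentration · V^b · laser power),
  normalization to µM-fluorescein-equivalent units, pixel-wise
  FAD/(NADH+FAD) maps with validity floor, epithelial summaries at 1/4, 1/2
  and 3/4 stack depth.
- **FLIM** — spatial binning to ≥10,000 photons/pixel, per-pixel fits of the
  periodic-excitation ("incomplete") bi-exponential
  f(t) = Σ A_k·exp(−t/τ_k)/(1 − exp(−T/τ_k)) convolved with the measured
  IRF, Poisson-weighted reduced χ² with a χ² < 1.5 acceptance filter,
  epithelial mean A1/A2, and phasor analysis at 80 MHz with IRF
  deconvolution plus a two-species chord check.
- **Histology** — Otsu segmentation of Ki67 and DAPI nuclei inside a traced
  region, 8-connected components, object-level co-localization, and the
  proliferation index (Ki67 ∩ DAPI)/DAPI.
- **Statistics** — wound size normalized to day 0, two-factor nested mixed
  ANOVA (`value ~ group*day + (1|mouse) + (1|mouse:location)`) with Tukey
  HSD, Pearson correlations with the exact t-based test, per-animal standard
  errors, and a deterministic markdown report.

## Worked example

The numbered drivers under `analysis/` run the whole study pipeline on
synthetic data and write their tables under `results/`. For example, FLIM
fitting at the stack midpoint (`analysis/04_flim_fitting.R`) prints:

```
spatially binned at level 2 (5x5 neighborhoods)
144 of 144 pixels accepted (chi2 < 1.5); mean chi2 0.964
mean tau1 542 ps (truth 536), mean tau2 3600 ps (truth 3679), mean A1/A2 1.120 (truth 1.2)
phasor cloud max distance from the two-species chord: 0.0201
```

i.e. decays generated with a 536/3679 ps lifetime pair at ~11,000 photons per
binned pixel are recovered to within a few percent, every pixel passes the
χ² filter, and the phasor cloud is consistent with a two-species (free/bound
NADH) mixture. The registration driver (`analysis/02_register_stacks.R`)
reports the per-channel discard fraction and the 3D channel offset, and the
redox driver (`analysis/03_redox_mapping.R`) recovers an ex vivo
base-to-tip epithelial gradient of 0.35 → 0.60:

```
ex vivo tongue redox: basal 0.3504, middle 0.4747, distal 0.6006
```

In code, one frame-rejection step looks like:

```r
library(mpmwound)
cfg <- acq_config(n_repeats = 50)
vol <- generate_wound_edge_volume(cfg)
seqn <- inject_motion_artifacts(vol, cfg, artifact_prob = 0.08)
reg <- register_sequence(seqn)
rep <- reject_frames(reg$scores)       # mean - 1 sd per depth
final <- assemble_final_stack(seqn, rep, reg$shifts)
```

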