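---
title: "Label-free metabolic imaging of wound healing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free metabolic imaging of wound healing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpmwound)
```

`mpmwound` analyzes repeated label-free multiphoton acquisitions of skin
wound edges: optical redox ratio maps from NADH and FAD autofluorescence,
NADH fluorescence-lifetime (TCSPC) fitting, Ki67/DAPI proliferation indexing,
and the longitudinal statistics tying them together. This vignette explains
the models behind each stage, the parameters that matter, what the synthetic
data generator does and does not emulate, and the numerical choices made
where the design was genuinely open.

## The measurement model

**Optical redox ratio.** NADH fluoresces only when reduced and FAD only when
oxidized, so the per-pixel ratio FAD/(NADH+FAD) of their (normalized)
autofluorescence intensities falls when glycolysis or biosynthesis raises the
intracellular NADH pool — as in proliferating keratinocytes at the wound
edge — and rises again as cells shift toward oxidative metabolism. The ratio
is bounded in [0, 1] by construction for non-negative intensities; pixels
whose summed intensity falls below a floor (default: 1% of the 99th
percentile of the normalized NADH volume) are marked invalid rather than
clipped, because a ratio of two near-zero signals is noise, not biology.

**Intensity normalization.** Comparing intensities across days requires
removing the acquisition settings. PMT gain is a power law of the applied
voltage, so imaging fluorescein standards of known concentration across
voltages gives
`intensity = prefactor · concentration · V^b · laser_power`,
log-log-linear with slope `b`. `fit_pmt_calibration()` estimates
(prefactor, b) by least squares on the log scale; `normalize_stack()` then
converts raw counts to µM-fluorescein-equivalent units. A voltage outside the
calibrated range warns (extrapolation of a fitted power law) but computes.
Because both channels are divided by the same gain law, redox ratios are
additionally robust to residual calibration error — this is verified, not
assumed, by the normalization-invariance tests.

**NADH lifetime.** Under 80 MHz excitation the 12.5 ns period is short
relative to the ~3.7 ns bound-NADH component, so fluorescence from previous
pulses persists. The periodic-excitation ("incomplete") bi-exponential model

$$f(t) = \sum_k A_k \frac{e^{-t/\tau_k}}{1 - e^{-T/\tau_k}}, \qquad t \in [0, T)$$

folds the pile-up in analytically: as $T \to \infty$ it reduces to the plain
bi-exponential, and it integrates over one period to $\sum_k A_k \tau_k$
exactly. The short component ($\tau_1$, amplitude $A_1$) is attributed to
free NADH and the long component ($\tau_2$, $A_2$) to protein-bound NADH; the
epithelial summary is the mean of per-pixel $A_1/A_2$ ratios over accepted
pixels — a mean of ratios, not a ratio of summed amplitudes.

**Phasors.** The first-harmonic Fourier coordinates $(g, s)$ of a decay at
the repetition frequency place mono-exponentials on the universal semicircle
$(g - \tfrac12)^2 + s^2 = \tfrac14$ and any non-negative mixture of two
species on the chord between the pure-species phasors. Dividing the decay's
phasor by the IRF's phasor deconvolves the instrument response. Two numerical
conventions matter and are fixed here: transforms evaluate at bin centers,
and the complex division is followed by a half-bin phase factor because the
discrete convolution theorem is anchored on the integer bin grid — without
it, deconvolved phasors sit rotated off the semicircle by half a bin
(≈0.025 at 64 channels), an order of magnitude above the identity checks the
test suite runs at 1e-3.

## Motion correction

Each location is acquired as `n_repeats` rapid z-stacks; breathing-scale
motion corrupts a subset of frames. The procedure: (1) average the repeats
per depth into an initial reference; (2) register every frame to its
reference slice by integer-pixel cross-correlation and record the correlation
maximum; (3) per depth, discard frames scoring below mean − 1 sd (sample sd,
single pass, score exactly at the threshold kept); (4) shift survivors into
register, crop to the common valid region — never zero-pad, so averages are
not diluted — and average; (5) co-register the two excitation channels by 3D
cross-correlation.

Correlation is the Pearson form computed over the overlap region of each
candidate shift (the cross term FFT-accelerated with zero padding; window
means and variances from integral images). The windowed form makes an exact
translation of the reference score exactly 1 at the true shift, which a
global normalization does not guarantee on smooth content. Registration is
integer-pixel by design, over a bounded search window (default ±6 px): the
small acquisition jitter is recoverable, while artifact translations larger
than the window cannot be "rescued" and score low. Rejection thresholds are
intentionally adaptive: at depths with artifacts the inflated sd pulls the
threshold far below the clean-score cluster, so clean frames survive; with
many repeats (the study design uses 50) depths without artifacts are rare,
keeping the false-rejection rate low. At much smaller repeat counts the
mean − 1 sd rule necessarily discards a tail of clean frames — a property of
the rule, visible in the `analysis/02` driver which runs 10 repeats.

## The synthetic-data generator

The generator is a 2.5-D procedural texture, not a light-transport
simulation: an epithelial compartment of Gaussian-blob "cells" advancing as a
tongue over a dim wound bed, dermis carrying an oriented fiber field (SHG)
under a smooth random envelope (the envelope breaks the sinusoid's
translational self-similarity, so a large shift of a dermal slice cannot
accidentally re-align), and granulation texture so no region is flat. NADH
and FAD channels are built from a shared radiance field L and the true redox
field R as `NADH = L(1−R)`, `FAD = L·R`, which makes the pixel-wise ratio of
the noiseless volume reproduce R to machine precision — the core consistency
invariant of the test suite. Depth attenuation is a single exponential
(default 150 µm length constant) applied equally to all channels, hence
ratio-preserving.

Defaults emulate the study conditions: 512×512 px over 584×584 µm (reduced
to 128×128 for desk-scale runs; tests use 48×48 where geometry allows), 5 µm
z-steps, 50 repeats (10 in the reduced default), 8% artifact probability,
artifact classes {large translation, intra-frame shear, intensity dropout}
each constructed to be detectable as low cross-correlation — translations
scale with the frame (25–45% of its smaller dimension, ≥10 px) because
respiration displaces the whole field of view. Poisson shot noise plus
Gaussian read noise (default sd 2 counts) on every frame; jitter uniform on
±2 px, circular so recovery can be exact.

The tongue's redox profile runs base → tip with defaults 0.35 → 0.6. The
default profile is plateau–ramp–plateau (uniform basal third, linear middle,
uniform distal third), reflecting a proliferative basal compartment and a
non-proliferative migratory tip with a transition between; a strictly linear
profile is available (`redox_profile = "linear"`). With the plateau profile
the regional means of the basal and distal thirds equal the endpoint values,
so recovered regional means are directly comparable to the generator's
endpoints.

What the generator does **not** emulate: optical point-spread functions,
hemoglobin/melanin absorption, keratin spectral crosstalk, non-rigid tissue
deformation, depth-dependent scattering anisotropy. Passing tests therefore
demonstrate that the *operators* are correct under the stated noise and
motion models, not that the pipeline is robust to every property of real
tissue.

## FLIM fitting: objective and numerics

Per-pixel histograms are spatially binned by summing (2n+1)×(2n+1)
neighborhoods (truncated at borders, so each input photon is counted at most
once and binned sums remain Poisson), with the smallest level whose median
masked pixel reaches 10,000 photons, capped at level 2 — the 5×5 kernel.
The fit minimizes the Poisson-weighted reduced chi-square

$$\chi^2_\nu = \frac{1}{n_{\mathrm{bins}} - p}\sum_t \frac{(h_t - (f \circledast \mathrm{IRF})_t)^2}{\max(h_t, 1)}, \qquad p = 6$$

over (A1, A2, τ1, τ2, IRF shift, constant background), convolution circular
over the period. Lifetimes and shift are optimized by bounded L-BFGS-B from
three fixed (τ1, τ2) starts — (300, 2500), (600, 3500), (900, 4500) ps, best
χ² kept, ties to the first — while amplitudes and background are profiled
out at every step by exact weighted non-negative linear least squares
(variable projection): the same objective, fewer nonlinear parameters, and a
deterministic result. Bounds: τ1 ∈ [50, 3000] ps, τ2 ∈ [800, 9000] ps,
shift ∈ ±5 bins. If one amplitude collapses to zero the decay is reported as
mono-exponential (active component as τ1, A2 = 0, τ2 = Inf). Pixels with
χ² ≥ 1.5 or failed convergence are excluded from summaries; χ² is computed
pixel-wise, with image medians available for reference.

Two deliberate numerical choices: (1) the TCSPC grid defaults to 64 channels
over the 12.5 ns period (195 ps bins, comfortably above the 0.25 ns IRF
width). The data-weighted chi-square underweights upward count fluctuations,
which at a fixed photon budget biases lifetimes increasingly low as the same
photons are spread over more channels; at 64 channels and 10,000
photons/pixel the simulated bias of both lifetimes stays under 5%, consistent
with the recovery properties the tests assert, whereas much finer grids
trade bin occupancy for resolution the 0.25 ns IRF cannot use. (2) The
acceptance-style fixtures generate 450 photons/pixel so level-2 binning lands
above the 10,000-photon floor rather than at its boundary, as the binning
protocol intends ("at least" 10,000).

## Histology

Otsu's threshold maximizes between-class variance on a 256-bin histogram of
the traced region's pixels (ties toward the lower threshold); components are
8-connected; objects under 20 px are removed. Otsu always returns *some*
split, so a channel with no stained nuclei would otherwise bisect its own
noise — and at ~50% suprathreshold density random pixels percolate into one
giant 8-connected component. A contrast guard therefore requires the class
separation to exceed 4 pooled within-class standard deviations; below it the
mask is empty. A DAPI nucleus counts as Ki67-positive when ≥25% of its pixels
fall inside the Ki67 mask — object-level co-localization; the fractional
criterion avoids single-pixel false positives and is configurable. No
watershed splitting of touching nuclei is attempted; two nuclei bridged by a
single diagonal pixel merge (documented 8-connectivity behavior).

## Statistics

Outcomes are analyzed independently on the long-format measurement table
(mouse × day × wound-edge location). The mixed model is
`value ~ group*day + (1|mouse) + (1|mouse:location)` — random intercepts for
animal and for location nested within animal — with type-III F tests.
Satterthwaite degrees of freedom are used (the method available in the
fitting stack and well calibrated here: the type-I error of the group test
over 500 null simulations sits inside [0.03, 0.08] at α = 0.05, asserted by
the acceptance suite). Tukey HSD runs over the group×day cell means with
family-wise adjustment. If the mixed model cannot be estimated the analysis
falls back, flagged, to a two-factor ANOVA on per-mouse cell means; a
constant outcome returns NA statistics without error. Power note: the
day-10 group contrast's standard error is dominated by between-animal
variance, so detection thresholds scale with the animal-level, not residual,
noise — the power fixture injects a 5× residual-sd effect, which Tukey flags
in ≥95% of runs. Pearson correlations report the exact two-sided t-based
p-value on n−2 df; per-animal standard errors are sd(per-animal means)/√n.
Wound areas are normalized to day 0 only. Boxplot summaries use type-7
(linear interpolation) quartiles with full-range whiskers.

## Problem sizes and determinism

Every generator is bit-reproducible given (config, seed), and each consumes
its seed through a documented draw order (the artifact mask is the first draw,
so its binomial count is recomputable). The test and acceptance fixtures use
reduced geometries chosen to exercise every code path at interactive scale:
48×48×5×50 frames for rejection, 16–20 px square lifetime images with
144–256 fitted pixels, 128×128 sections for redox, 500 simulations for the
type-I calibration. The full 512×512×51×50 study geometry is available by
configuration.

## Known limitations

- Integer-pixel registration only; no sub-pixel interpolation, no non-rigid
  or line-by-line repair of sheared frames (they are rejected, not repaired).
- The rejection rule over-discards at small repeat counts (see above).
- The data-weighted chi-square estimator carries a small low-side lifetime
  bias at low bin occupancy; the per-pixel A1/A2 mean inherits a ~2–3%
  low-side bias at exactly 10,000 photons.
- Epithelial masks are inputs (ground truth or traced volumes); no automatic
  epithelium segmentation is attempted, matching the traced-region protocol.
- No correction for the in vivo/ex vivo redox offset is applied; the two
  preparations are summarized separately.
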