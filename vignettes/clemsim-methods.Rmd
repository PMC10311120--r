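---
title: "Automated CLEM registration by in-silico chromatin labeling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated CLEM registration by in-silico chromatin labeling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(clemsim)
```

## The registration problem

Correlative light and electron microscopy (CLEM) images the same resin
section twice: first with super-resolution fluorescence, then with scanning
EM. The two acquisitions land in different coordinate frames — the section
is remounted, rotated, and imaged at a different pixel size — and the two
modalities have such different contrast that direct correlation-based
alignment fails. In practice, a DNA stain (Hoechst) marks chromatin, and
the dense heterochromatin puncta it lights up are also electron-dense, so
they appear dark in the EM image. Those puncta are the only features
present in both modalities, and manual registration drags the fluorescence
over the EM until the puncta coincide.

`clemsim` automates this in three stages:

1. **In-silico labeling.** A small convolutional network (a U-Net
   regressor) is trained on manually aligned EM/chromatin pairs to predict
   a "virtual" chromatin image from the EM image alone. The prediction
   lives exactly in the EM coordinate frame.
2. **Similarity registration.** The measured chromatin channel (moving
   image) is registered to the virtual chromatin image (fixed image). Both
   are now the *same* modality, so ordinary feature matching and
   correlation work. The transform class is a 2D similarity — rotation
   $\theta$, isotropic scale $s$, translation $(t_x, t_y)$ — which models a
   remounted flat section; reflections are excluded and reported as an
   error (`REFLECTION_REQUIRED`), because a flipped section is a sample
   problem, not a registration problem.
3. **Transfer.** The recovered transform is applied to every other
   fluorescence channel, which carry the biological signal of interest but
   no registration information of their own.

All transforms map moving coordinates into fixed (EM) coordinates, act on
`(x, y)` points with x = column, y = row, 0-based, about the origin unless
built with `transform_about_center()`; warping resamples with the inverse
map. Fixing this convention once removes the most common class of
registration bugs.

## The similarity estimator

Given point correspondences $(z_i, w_i)$ (moving, fixed; written as
complex numbers), the least-squares similarity without reflection has the
closed form

$$a = \frac{\sum_i \tilde w_i \overline{\tilde z_i}}{\sum_i |\tilde z_i|^2},
\qquad s = |a|, \quad \theta = \arg a, \quad
t = \bar w - a \bar z,$$

with $\tilde z, \tilde w$ the centered points. If the reflected model
correlates strictly better ($|\sum \tilde w_i \tilde z_i| >
|\sum \tilde w_i \overline{\tilde z_i}|$) the fit aborts rather than
returning the best non-reflected transform, which would be silently wrong.
Two exact correspondences determine the transform; the estimator
reproduces constructed transforms to $10^{-9}$ in every parameter, which
the test suite asserts over the scale range $s \in [0.5, 2]$.

Robustness comes from RANSAC over minimal samples of 2 correspondences
(a similarity has 4 degrees of freedom), consensus at a 3 px residual
tolerance, ties broken by inlier RMS. Before the final least-squares refit
the tolerance is tightened to $6\times$ the robust (MAD) residual scale of
the winning consensus: an outlier that lands inside the raw 3 px tolerance
by chance would otherwise bias the refit by ~0.1 px. With noiseless
inliers this collapses to a numerical floor ($10^{-6}$ px) and recovery is
exact.

## Features: puncta as fiducials

Heterochromatin puncta are round, bright (in fluorescence and in the
virtual channel), and 100–250 nm in radius — exactly the feature class of
multiscale Laplacian-of-Gaussian blob detection. `detect_blobs()` finds
maxima of the scale-normalized response $-\sigma^2 \nabla^2 (G_\sigma * I)$
over position and scale ($\sigma$ log-spaced, default 1.5–8 px, 6 scales),
localizes them by a quadratic fit (≈0.1 px on rendered spots), and reports
radius estimates as $\sigma\sqrt2$.

Because all puncta look alike, intensity descriptors alone cannot
discriminate them. Each keypoint therefore carries a rotation-invariant
descriptor built from two parts: mean intensities over 8 concentric rings
(local appearance) and log-distances to the 3 nearest other keypoints
normalized by the set's mean pairwise distance (geometric context,
invariant to rotation and global scale). Matching is mutual-nearest-
neighbor with a strict Lowe ratio test (default 0.8); ambiguous matches
between look-alike puncta are dropped rather than guessed.

When fewer than `min_inliers` (3) consistent matches survive — few puncta,
poor prediction — registration falls back to an exhaustive search:
for every rotation on a grid (default 2° steps over the full circle, about
the image center) and every scale on a grid, the translation is taken from
the FFT cross-correlation peak, candidates are scored by zero-normalized
cross-correlation (NCC) over valid pixels, and the best is kept. The
search runs on a 2×-downsampled pyramid level when images exceed 128 px
and the result is lifted back. Two refinements follow in either path:

- **Landmark refit**: detected blobs are projected through the candidate,
  greedily paired with the nearest fixed blobs within tolerance, and the
  similarity is refit in closed form (two rounds). This recovers sub-pixel
  accuracy no search grid can reach.
- **`NCC_LOCAL`**: bounded Nelder-Mead maximization of the NCC over the 4
  parameters, accepted only if it improves the full-resolution score.

A sub-pixel cross-correlation offset (quadratic fit) is accepted only when
it actually improves the NCC over the integer peak; for an exact integer
shift the correlation surface is truncated asymmetrically and the
quadratic fit is biased, while the integer peak is exact.

Failure is a result, not an exception: `register_planes()` returns
`status` `OK` (≥3 inliers and NCC did not degrade), `LOW_FEATURES`,
`NO_CONSENSUS`, or `DEGRADED`, with NCC before/after for audit.

## The synthetic scene generator

No public srAT data ships with the package, so all end-to-end claims are
made on simulated correlative scenes with exact ground truth
(`scene_params()`, `sample_scene()`, `render_em()`,
`render_fluorescence()`):

- **Geometry**: 256×256 px at 25 nm/px (a 6.4 µm field). The pixel size is
  chosen so the benchmark's standard 3125 nm shift is exactly 125 px,
  making the shift perturbation lossless. Two elliptical nuclei
  (semi-axes 1.25–2.25 µm) sit in the central field; each contains 3–6
  non-overlapping puncta (radius 100–250 nm) — at least three, because a
  similarity transform is only well-posed with three or more landmarks in
  the field of view.
- **EM render**: mid-gray cytoplasm with smooth low-frequency texture,
  slightly darker nucleoplasm, puncta as *dark* soft-edged disks
  (electron-dense chromatin), additive Gaussian noise (sd 0.03).
- **Fluorescence render**: puncta as *bright* isotropic Gaussian spots
  (PSF sigma 60 nm ≈ a SIM-scale PSF) over a 0.05 background, with scaled
  Poisson shot noise (200 photons per intensity unit) and Gaussian read
  noise (sd 0.01).
- **Misalignment**: one global similarity per scene, drawn uniformly from
  ±15°, scale 0.98–1.02, shift ±625 nm, about the image center — the
  magnitude of error left after coarse manual placement of a serial
  section. Global-only is deliberate: the registration model is a
  similarity, and the simulator matches the model class.

Scenes are pure functions of `(params, seed)`; renders are byte-identical
across runs. What the simulator does **not** emulate: realistic EM
ultrastructure (membranes, organelles), section folds and local
deformation, chromatin texture beyond discrete puncta, and channel
crosstalk. Passing the synthetic benchmark therefore demonstrates that the
*registration machinery* is correct and accurate under the stated noise,
not that the network will predict chromatin well on any particular real
dataset — on real data, prediction quality is the dominant risk and
retraining on 30–40 aligned pairs from the same experiment is the expected
workflow.

## The network and its training

The regressor is a plain 2D U-Net: `depth` (default 3) levels of one 3×3
convolution + ReLU and 2×2 mean pooling, a bottleneck convolution, and a
mirrored decoder with nearest-neighbor upsampling, skip concatenation and
a linear 1×1 output head. Channels double per level from `base_filters`
(default 16). The default loss is MAE (L1), the optimizer Adam
(learning rate $10^{-3}$), and training samples aligned 64-px patch pairs.
The production-scale schedule is 150 epochs at batch size 8; the tests and
the acceptance script use a reduced desk-scale preset (30 pairs, 2 patches
per pair, 20 epochs) that trains in about three minutes on one CPU and
reaches a median Pearson correlation of ~0.9 between predictions and the
noiseless ground-truth chromatin on held-out scenes (gate: > 0.7).

The implementation is native R with two compiled primitives (im2col
gather and its scatter transpose, in `src/im2col.cpp`); convolutions are
single BLAS matrix products over index-stacked batches. Backpropagation is
verified against numerical differentiation in the test suite. A single
integer seed drives patch sampling, weight initialization and shuffling;
seeded runs reproduce the loss history exactly on the same platform
(bit-reproducibility across BLAS builds is not promised).

Preprocessing is part of the model artifact: the configured EM
preprocessing (default: global 256-bin histogram equalization followed by
(1, 99.8) percentile normalization) and the target normalization are
embedded in the saved model and re-applied at prediction time, so there is
no train/predict skew. Global (not adaptive) equalization is used for the
EM input because it harmonizes contrast between acquisitions; for the
*registration* inputs (measured and predicted chromatin) the pipeline uses
percentile normalization only — equalizing a sparse spot image stretches
background noise across the intensity range and floods the blob detector
with false maxima.

Prediction tiles large images (tile and overlap configurable). Each tile
is run with `3·2^depth − 2` pixels of surrounding image context (the
network's receptive-field radius, rounded to the pooling grid), and tile
interiors are stitched disjointly, so tiled and single-pass predictions
agree to floating-point precision away from the image border.

## The benchmark

`run_benchmark()` implements the known-perturbation protocol: for each
held-out scene, the aligned chromatin image is perturbed by a known
transform — identity, a 3125 nm shift in x, or a 90°/180° rotation about
the center (rotations and integer shifts applied losslessly with
nearest-neighbor resampling) — the full predict-and-register workflow
runs, and the recovered transform composed with the perturbation is
compared to the identity. The error measure is the mean absolute per-axis
displacement, evaluated at the scene's puncta coordinates and converted
to nm; puncta are the biologically meaningful landmarks, and this
definition is explicit and directly testable. A registration is a success
when its status is `OK` and both per-axis errors are at most the
threshold, default 250 nm: successful registrations in this regime land
within tens of nm while failures are off by several hundred nm or more,
so any threshold in that gap separates the same two populations.

With a perfect-predictor stand-in (`oracle_model()`), the benchmark
isolates the registration stage: per-axis errors stay below 12.5 nm
(half a pixel). With the desk-scale trained network, 10 scenes × 4
perturbations at threshold 250 nm give a success rate of ~0.9
(gate: ≥ 0.75); `scripts/acceptance.R` recomputes these numbers from
scratch.

## Numerical choices and edge cases

- Percentiles use linear interpolation between order statistics
  (`type = 7`), and percentile normalization never clips, so it is exactly
  affine and invertible. Constant images are hard errors in normalization
  and equalization, and produce `LOW_FEATURES` (never an exception) in
  registration.
- Missing pixel size is a hard error in `read_image()`: nm-scale error
  reporting is meaningless without it. Because the TIFF writer available
  to R cannot emit resolution tags, the package writes them itself into
  the IFD (px/cm rationals), plus an ImageDescription range annotation
  that makes float data round-trip; integer data (camera counts) is
  stored as 16-bit and round-trips exactly.
- Warping fills out-of-source pixels with 0 and tracks a validity mask;
  NCC is computed over valid pixels only.
- RANSAC ties are broken by lower inlier RMS; the sampler is seeded from
  the registration config.
- `ROT_90`/`ROT_180` on square images and integer shifts are applied with
  nearest-neighbor resampling and are exactly invertible; everything else
  uses bilinear interpolation.

## Known limitations

- Similarity-only: no affine shear, no local deformation, no flip
  recovery. Sections with folds or tears violate the model.
- The exhaustive fallback assumes the rotation is on its grid (default 2°)
  and the scale near its grid values; pathological scale errors outside
  the configured grid are not recovered.
- Fewer than three detectable puncta in the field of view make the
  problem ill-posed; the tool reports `LOW_FEATURES` rather than guessing.
- The native network is CPU-oriented and desk-scale; it is not a
  replacement for GPU training on large real datasets, and transfer of a
  model across experiments with different EM contrast is expected to need
  retraining.
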