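---
title: "Electroacoustic tomography with learned limited-angle correction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electroacoustic tomography with learned limited-angle correction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eatomo)
```

## The imaging problem

Electroacoustic tomography (EAT) images the energy deposited by nanosecond
pulsed electric fields (nsPEF): the absorbed electric energy launches
ultrasound transients, a linear transducer array records them, and
delay-and-sum back-projection turns one view's channel data into an image of
the initial pressure. A single linear array sees the object from one side
only, so the single-view reconstruction carries severe limited-angle
distortions: arc-shaped streaks and an anisotropic point-spread that smears
structure tangentially to the missing aperture.

The workflow in this package addresses that in three stages:

1. **Simulation.** Two-electrode energy-deposition phantoms
   (`generate_phantom()`) and a linear forward model of the array
   measurement (`simulate_channels()`).
2. **Reconstruction.** Per-view delay-and-sum back-projection
   (`backproject()`); a full-view ground truth built by rotating each
   single view back into the object frame and averaging
   (`composite_full_view()`), emulating an acquisition in which the
   electrodes rotate through `n` equally spaced views over 360 degrees
   while the array stays fixed.
3. **Enhancement.** A modified U-Net (`train_enhancer()`) trained with a
   structural-dissimilarity loss to map single-view images to
   full-view-quality images, evaluated with RMSE, PSNR, SSIM and
   iso-pressure DICE (`evaluate_pairs()`).

## Phantom model

No closed-form expression exists for the energy pattern deposited around a
real electrode pair, so the generator uses the simplest physically shaped
stand-in: a two-dimensional two-point-charge log-potential dipole,
$\phi(r) = \ln\max(\lVert r-a\rVert,\sigma) - \ln\max(\lVert r-b\rVert,\sigma)$,
whose energy density $w \propto V^2\,\lVert\nabla\phi\rVert^2$ reproduces
the two-lobed falloff around the tips. Three parameters control it:

* `voltage` (V/cm) — the field-intensity scale. The map scales exactly with
  `voltage^2`; the proportionality constant is 1 in arbitrary pressure
  units because every downstream metric operates on per-image min-max
  normalized intensities, making the absolute scale immaterial.
* `tip_sigma` (mm, default 0.8) — Gaussian smoothing width; also the lower
  clamp on tip distances, so each tip occupies a few voxels at the default
  grid spacing instead of a singularity. The remaining spikes are clipped
  at the 99.5th percentile before rescaling.
* `echo_amplitude` (fraction of peak, default sampled in 0.05–0.25) — two
  Gaussian blobs added on the tip–tip axis half a tip-separation beyond
  each tip. They model the echo artifacts seen between electrodes as an
  additive nuisance the network must learn around, not as propagated
  reflections; solving the echo physics is deliberately out of scope.

`sample_config()` draws tip separation (15–35% of the field of view),
midpoint (within ±15% of center), axis angle, voltage and echo amplitude
uniformly, mirroring the varied distances and angles relative to the array
that make datasets differ.

## Forward model and its adjoint

The measurement operator is a discrete spherical-spreading delay-and-sum
projector, not a wave-equation solver: the source is rotated by
`-view_angle` about the rotation center (bilinear interpolation, zero
fill), then each voxel's amplitude is split linearly between the two time
bins adjacent to its time of flight to each element, weighted
$1/\max(d, \text{spacing})$. The rationale is that reconstruction is
back-projection, so a *matched* linear forward/adjoint pair is the minimal
model that makes the whole pipeline testable while producing realistic
limited-angle distortion. The adjoint uses the exact transpose of every
step, including the transpose of the bilinear rotation (splatting), so the
pair passes a dot-product test at machine precision rather than merely to
interpolation accuracy.

Defaults follow the acquisition chain: 128 elements, 40 MHz sampling,
optional 12-bit quantization (deviation provably at most full-scale/4096),
sound speed 1480 m/s (water at room temperature). Pitch 60/128 mm is
inferred from a 60 mm-aperture probe; standoff 40 mm is an engineering
choice — neither is printed anywhere authoritative, and both are
configurable. The record length defaults to the farthest voxel's time of
flight plus 8 guard samples. An optional first-difference time filter
approximates the derivative character of acoustic transients; it is off by
default so the operator stays exactly matched to its adjoint.

Conventions, stated once and asserted in tests: angles in degrees,
counter-clockwise; images row-major with world x along columns; voxel
centers are the reference points; the forward model rotates the *source* by
`-view_angle` (electrodes rotate, array fixed) and compositing rotates
images by `+view_angle` back into the object frame.

## Reconstruction choices

Back-projection is adjoint-type delay-and-sum, normalized by the element
count, without universal-back-projection solid-angle weighting — the
simplest operator consistent with pronounced limited-angle arcs and an
exact adjoint for testing. Negative values are kept; normalization to
[0, 1] happens only inside metrics and training. The full view is composed
in the image domain ("rotating and averaging the single-view images"), the
literal reading of the acquisition protocol.

## Metrics

All metrics operate on per-image min-max normalized pairs. A constant image
cannot be normalized; inside batch evaluation it becomes the zero image
with a warning rather than an error. RMSE is the root mean squared voxel
difference; PSNR is $20\log_{10}(1/\text{RMSE})$ with peak 1, capped at a
flagged 99 dB sentinel so aggregates of perfect pairs stay finite. SSIM
uses the canonical constants (Gaussian window 11×11, $\sigma=1.5$,
$K_1=0.01$, $K_2=0.03$, dynamic range 1, population covariance) with the
SSIM map cropped by the window radius before averaging — every retained
window then lies fully inside the image, which makes the boundary padding
irrelevant and the value match reference implementations exactly.
Iso-pressure DICE binarizes both images at a level in (0, 1) — under
min-max normalization, thresholding at `p` and at `p` percent of max
coincide — with the conventions DICE = 1 when both masks are empty and 0
when exactly one is. Aggregates report mean ± population standard
deviation, stated explicitly so "mean ± sd" rows are well defined at any
sample size.

## The enhancer

The network is an encoder–decoder with skip connections: two
convolution(3×3) + batch-normalization + ReLU blocks per scale, 2×2
max-pooling down, nearest-neighbour upsampling plus concatenation up,
dropout (rate 0.5) at the U-bottom only, and a linear 1×1 output. Exact
filter counts and depth are free design choices; the default sizing is
the canonical one
(depth 4, 32 base filters doubling per level, 256×256 input) with a
reduced preset (depth 2, 8 filters, 64×64) for CPU-scale work. All layers
and their gradients are implemented directly on GEMM-based im2col
convolution kernels; training needs no external framework.

Training follows the stated recipe: Adam, learning rate 0.0007, batch size
1, structural-dissimilarity loss. DSSIM is defined as $1-\mathrm{SSIM}$
(the simplest reading; any positive affine rescaling is
optimization-equivalent), computed with exactly the same windowed SSIM as
the evaluation metric, and its gradient is analytic — the Gaussian window
filter is self-adjoint under zero padding, and only cropped-region SSIM
values enter the mean, so the gradient is exact and is
verified against finite differences in the tests. Inputs and targets are min-max normalized per image;
the final activation is linear with outputs clamped to [0, 1] only at
evaluation time, keeping gradients unsaturated and the clamp explicit. The
best checkpoint is selected by validation loss. No data augmentation is
used.

With batch size 1, the batch statistics of a batch-normalization layer
*are* the per-sample spatial statistics; inference reuses the same
per-sample statistics instead of running averages. This keeps prediction
deterministic and avoids stale running estimates on short synthetic runs,
at the cost of a mild train/test asymmetry relative to conventional
batch-norm inference.

Splits are always by dataset (electrode configuration), never by view, so
no configuration leaks between training, validation and test. The
full-scale protocol (40/6/10 datasets × 60 views → 2400/360/600 samples;
training voltages 1200–2000 V/cm, test at 2400 V/cm) is declared by
`paper_preset()`; the test suite exercises the desk preset.

## Problem sizes used by the test suite

The desk preset — 10 train / 2 val / 2 test datasets, 16 views, 64×64
grid, 16-element array, reduced U-Net, 20 epochs, seed fixed — is the
package's chosen benchmark scale: large enough that the enhancer must
actually learn the arc-artifact structure across unseen electrode
configurations, small enough to train on one CPU in minutes. Training
voltages are sampled in [1200, 2000] V/cm and test phantoms sit at
2400 V/cm, so the held-out evaluation simultaneously measures
configuration and voltage generalization. Operator-level checks run on
32×32 grids with 16 elements, where a dense matrix of the forward operator
is cheap enough to serve as a brute-force oracle.

## What the synthetic data do and do not show

The generator emulates the acquisition geometry (rotating electrode pairs,
fixed linear array, equally spaced views), the voltage protocol, echo-like
nuisance structure, and DAQ quantization. It does not emulate transducer
bandwidth or directivity, frequency-dependent attenuation, coupling-film
effects, tissue heterogeneity (the reference experiments use a homogeneous
water tank), electrical noise, or the true wave physics of inter-electrode
echoes. Passing tests therefore demonstrate that the pipeline is
self-consistent and that the enhancer corrects the limited-angle
distortions of *this* forward model across unseen configurations and
voltages — not that the trained weights transfer to experimental data.
A purely structural training loss also concentrates the improvement on
structural metrics: at desk scale, SSIM and iso-contour DICE improve on
held-out configurations while the intensity-scale metrics (RMSE, PSNR)
need not, and the two-arm report keeps both visible.

## Numerical notes and known limitations

* Bilinear rotation with zero fill loses mass where content crosses the
  grid boundary; compositing is exact about the rotation center, and the
  composite's voxel sum equals the mean of the de-rotated views' sums to
  machine precision.
* A rotationally symmetric phantom makes every view equivalent: channel
  data and single-view images coincide across angles to within bilinear
  interpolation error (about 1% of peak for a ring resolved at ~3 voxels),
  and the composite equals the rotation-average of any single view at the
  same tolerance. The composite does *not* equal any one de-rotated view:
  a single one-sided view carries the anisotropic limited-angle
  point-spread — exactly the distortion the enhancer corrects — so that
  difference is order-of-peak by design, for any aperture or standoff.
* Quantization uses a signed mid-tread quantizer at full scale
  `max(abs(signal))`, giving the `full_scale / 2^bits` worst-case bound
  that the tests assert.
* PSNR of identical images is reported as a capped, flagged 99 dB.
* Degenerate inputs: constant images normalize to zero with a warning in
  batch paths and error in direct calls; empty view lists, mixed grids,
  duplicate angles, out-of-view electrode tips and too-short time records
  raise named validation errors.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes, from scratch:
the operator adjointness error, point-source recovery error,
symmetric-phantom view invariance, the quantization bound ratio, and the
desk-scale two-arm metric table (RMSE/PSNR/SSIM/DICE for raw single-view
and enhanced images against the full-view ground truth, plus the SSIM and
DICE gains). Every random draw is derived from the one `--seed` argument.
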