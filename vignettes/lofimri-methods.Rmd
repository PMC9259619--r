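---
title: "Accelerating low-field MRI with a residual U-net: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerating low-field MRI with a residual U-net: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Low-field MRI (here, the 0.1 T regime) trades signal-to-noise ratio for cost
and accessibility. The SNR deficit is usually paid back through signal
averaging, which inflates acquisition times; undersampling the phase-encode
directions of k-space shortens the scan by the acceleration rate R, at the
cost of blur and aliasing in the naive zero-filled reconstruction. `lofimri`
implements a complete desk-scale version of a data-driven remedy: train a
2-channel residual U-net to map zero-filled complex reconstructions back to
fully sampled complex images, with variable-density Gaussian sampling
patterns, joint real/imaginary geometric augmentation to compensate a small
training set, and an ROI-masked evaluation protocol for magnitude and phase.

Because clinical low-field raw data are not publicly distributable, the
package ships a seeded synthetic-phantom generator that emulates the
statistical structure of a small-matrix gradient-echo limb acquisition.
Every stage of the pipeline, including the headline comparison between
zero-filled and learned reconstruction, runs on these phantoms.

## The phantom generator

`generate_phantom()` draws, from a single seed:

* a convex elliptical "limb" support (semi-axes about 0.65–0.78 of the
  field of view, mildly modulated across slices), with exact zero magnitude
  outside — background voxels contain noise only;
* `n_structures` elliptical or annular structures with log-uniform semi-axes
  between 3% and 22% of the field of view, random orientation and
  intensities in `intensity_range`, painted over a smoothly shaded base
  tissue; log-uniform axes give the mix of coarse and fine spatial scales
  that probes high-frequency recovery;
* a per-slice second-order polynomial phase in normalized in-plane
  coordinates, with coefficients varying linearly across slices; an optional
  wrap term adds a three-cycle linear ramp so wrapped-phase behaviour can be
  exercised;
* i.i.d. complex Gaussian noise, each component with standard deviation
  `noise_sigma` times the peak magnitude, added everywhere in image space.
  White image-space noise is the right model when the receive chain is
  dominated by electronics rather than sample noise, as at very low field.

The default matrix is 128 × 115 × 9 at 1.2 × 1.2 × 6.3 mm voxels, matching
a compact low-field wrist protocol. No quantitative SNR is published for
such acquisitions, so `noise_sigma = 0.05` (peak SNR ≈ 20) was fixed once
as a realistic low-field operating point; it is a free parameter of the
generator, not a measured value. The generator does not model relaxation
contrast, B0 inhomogeneity, gradient nonlinearity or coil profiles, so
passing tests demonstrate correct recovery of piecewise-smooth complex
images under the stated noise model — not performance on in vivo data.

## k-space conventions

All transforms are centered, unitary FFTs (`fft_centered()` /
`ifft_centered()`): Parseval's identity holds to machine precision and the
DC sample sits at 0-based index `floor(n/2)`. Acquired k-spaces are
zero-filled to a square in-plane matrix (115 → 128 lines) before the network
sees them; the odd excess of 13 lines is split 6 on the low-index side and
7 on the high side, a fixed documented convention that `crop_kspace()`
inverts exactly. Normalization divides a 3D k-space by the standard
deviation of its complex samples (computed after zero-filling and
augmentation, in the preprocessing order) and keeps the scale so
reconstructed magnitudes can be expressed in the original units.

## Sampling patterns

`generate_gaussian_pattern()` builds binary masks over the acquired
(ky, kz) = 115 × 9 phase-encode grid. The `CL` ky lines nearest the center
are fully sampled; the remaining budget of `floor(ny*nz/R) − CL*nz` points
is a weighted draw without replacement, with weights proportional to a
separable Gaussian of standard deviations `sigma_y*ny` and `sigma_z*nz`
samples. The draw uses Gumbel-top-k ordering, which yields the exact budget
in one pass and is reproducible from the seed. Two accounting consequences
are worth noting:

* the masks are defined on the acquired 115-line grid, where the degenerate
  low-pass pattern (CL = 23, `sigma_y = 0`) achieves exactly R = 5
  (115/23 = 5); when the preprocessing order requires masking the
  zero-filled 128-line k-space, `embed_pattern()` places the mask centrally
  with the same 6/7 padding convention, and the padded lines are never
  sampled;
* `sigma = 0` collapses the Gaussian onto the center, so any budget beyond
  the center lines is a parameter error rather than a silent fallback.

`sigma` values are interpreted as fractions of the axis length — the
conventional reading of unitless pattern widths like 0.10 or 0.20 on grids
of fixed size.

## Augmentation

`draw_transform()` selects, per draw, transformations uniformly from
\{shift, horizontal flip, vertical flip, shear, zoom, rotation\} with
parameter ranges of ±50 pixels, [0°, 45°] shear, [75%, 125%] zoom and
[0°, 360°] rotation. Two draws are composed by default (`n_ops = 2`),
reflecting the use of two augmentation functions applied jointly; a single
draw is available through the configuration. The zoom range is read as
[75%, 125%]: a typographic inversion of the upper bound (printed elsewhere
as "1.25%") would make the transformation degenerate.

`apply_joint()` composes the selected maps into one affine transform about
the slice center and warps the real and the imaginary part with the
identical inverse-map bilinear interpolation, zero-filled outside the
original support. The warp is written so that exact cases stay exact:
integer shifts, flips, and rotations by multiples of 90° reduce to grid
permutations (via `cospi`/`sinpi` and degenerate bilinear weights), which
the test suite exploits as oracles. On very small volumes a ±50-pixel shift
can empty the field of view entirely; the dataset builders detect the
resulting degenerate (zero-variance) k-space and redraw the transform from
a derived seed, keeping pair counts deterministic.

Training pairs follow the preprocessing order: augment in image space →
FFT → apply the mask (input side only) → normalize both sides by the fully
sampled k-space standard deviation (one shared scale per pair) → inverse
FFT → split into per-slice 2-channel (real, imaginary) slices.

## The residual U-net

`build_model()` constructs, from `network_config()`:

* an encoder of `depth` sequences [conv 3×3 → ReLU → conv 3×3 → ReLU →
  max-pool 2×2], filters doubling from `base_filters` (64 → 512 at the
  default depth 4);
* a decoder of `depth` sequences [2× nearest-neighbour upsample → skip
  concatenation → conv 3×3 → ReLU → conv 3×3 → ReLU];
* a final 1×1 convolution with 2 filters mapping the `base_filters`-channel
  tensor to the real and imaginary outputs;
* when `residual = TRUE`, an identity shortcut adding the input to the
  final convolution's output, so the convolutional path learns the
  correction to the zero-filled image.

Choices where the architecture description leaves freedom: ReLU follows
every 3×3 convolution in both paths (symmetric variant); upsampling is
nearest-neighbour followed by convolution (transposed convolution was
considered and dropped to keep the hand-written backpropagation surface
small); the bottom of the U is the fourth encoder sequence's pooled output
(no separate wider bottleneck level); all convolutions use "same" padding
so the 128 × 128 in-plane size is preserved; spatial dimensions must be
divisible by `2^depth`.

Weights are He-uniform, seeded, with one deliberate exception: the final
1×1 convolution of a residual model is initialized to zero, so training
starts exactly at the identity map — the network's first prediction is the
zero-filled image itself and optimization only ever improves on that
baseline. This is a standard residual-network initialization and removes a
burn-in phase in which the loss recovers from a randomly initialized output
head.

The layers are implemented as cache-blocked im2col + GEMM primitives
(RcppArmadillo) with analytically derived adjoints; the test suite verifies
every gradient against central finite differences and the forward pass
against a direct convolution oracle.

Training (`train_unet()`) minimizes the mean squared error over both
channels with RMSProp (decay 0.9, epsilon 1e-7) starting at learning rate
1e-3, validates every epoch, multiplies the learning rate by 0.5 after 5
(configurable) epochs without validation improvement, and returns the
parameters with the best validation loss. The epoch ceiling is 2000 by
default; the scaled-down studies below use far fewer.

## Evaluation protocol

All metrics are computed per slice inside a region of interest derived from
the reference magnitude only: threshold at 10% of the slice maximum, binary
closing then opening with a disc of radius 2 (the opening removes isolated
noisy pixels). Two protocol details are the package's own:

* **Signal-free guard.** Relative thresholding cannot reject a pure-noise
  slice (the maximum of n Rayleigh draws is ≈ 4.4σ, so 10% of it sits well
  inside the noise bulk and most pixels survive). `compute_roi_mask()`
  therefore first estimates the noise scale from the lower quartile of the
  magnitudes (Rayleigh q25 = 0.7585σ) and returns an empty mask when the
  slice maximum does not exceed the extreme-value bound
  σ·(√(2 log n) + 1.5) for pure complex noise. Slices whose ROI covers less
  than `min_signal_fraction` (default 2%) of the slice are then excluded
  from all aggregates — the noise-only slice exclusion rule.
* **SSIM inside the mask.** SSIM uses 7×7 uniform windows (stride 1,
  K1 = 0.01, K2 = 0.03, dynamic range = maximum of the reference within the
  ROI) centered on ROI pixels, with window moments computed over the ROI
  pixels of each window only; reconstruction pixels outside the mask are
  never read, and on a full-image ROI the definition reduces to standard
  uniform-window SSIM. The SSIM numerator uses the standard
  (2σ_AB + C2) covariance term — the form under which identical images
  score exactly 1.

PSNR is `20·log10(max(ref over ROI)/RMSE)` with identical images flagged as
infinite and dropped from aggregates; NRMSE normalizes the RMSE by the ROI
mean of the reference. Gradient sharpness G — the only reference-free
metric — convolves the magnitude with 3×3 Sobel kernels (replicate padding,
so constants are exactly gradient-free) and averages √(Gx²+Gy²) over the
ROI; it is rejected on phase input, where wrap discontinuities dominate.
Phase metrics are computed on the wrapped phase in (−π, π] without
unwrapping; phase PSNR is reported for table parity but is advisory, since
the wrapped-phase maximum is not a meaningful dynamic range. Aggregation is
mean ± standard deviation across kept slices (per-slice lists are exposed so
any external significance test can consume them; rank-based testing of
method differences is left to standard library routines by design).

## The scaled-down study

`run_study()` executes the full retrospective protocol in memory. The
default desk-scale conditions, fixed once:

* 10 phantom volumes split 8/2 into training/validation at the volume level
  (slice-level splits would leak), plus 3 held-out test volumes (27 test
  slices);
* the fivefold pattern with CL = 7, σy = 0.10, σz = 0.20 on the 115 × 9
  grid;
* one unaugmented plus two augmented copies of each training volume —
  216 training slices;
* a reduced residual U-net (depth 3, 16 base filters, ~300k parameters)
  trained for 12 epochs with batch size 8 and plateau patience 3 — small
  enough to train on one CPU in minutes, deep enough to express a
  multiscale deblurring correction.

The study reports per-slice ROI-masked magnitude PSNR for the zero-filled
baseline and the trained model on the held-out slices, their medians, the
reference-free gradient sharpness of both reconstructions, and a paired
one-sided sign test of the hypothesis that the model's per-slice PSNR
exceeds the baseline's. `scripts/acceptance.R` re-runs exactly this
computation from a command-line seed.

## Numerical notes and limitations

* Determinism: every stochastic stage draws from a named stream derived
  from one master seed (phantoms, masks, transforms, split, initialization,
  shuffling), and all generators restore the caller's RNG state. Identical
  seeds give bit-identical phantoms, masks and initial weights; training is
  deterministic up to BLAS reduction order.
* The k-space standard deviation used for normalization includes the
  zero-filled entries, following the stated preprocessing order; the scale
  is therefore grid-dependent, which is immaterial because reference and
  reconstruction always share it.
* `normalize_kspace()` refuses constant (zero-variance) k-space;
  `generate_gaussian_pattern()` refuses budgets its density cannot fill;
  empty ROIs signal slice exclusion rather than erroring inside metric
  aggregation.
* The training loop holds all pairs in memory (a 216-slice study needs a
  few hundred MB); the implementation targets small low-field matrices, not
  large clinical volumes.
* Phantom results do not transfer to in vivo claims: the generator's
  piecewise-smooth magnitude favours deblurring-style corrections, and no
  anatomy, contrast mechanism or system imperfection is modelled.
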