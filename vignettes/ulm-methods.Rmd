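---
title: "Microbubble localization for ULM: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbubble localization for ULM: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Ultrasound localization microscopy (ULM) reconstructs microvasculature far
below the diffraction limit by detecting individual microbubble (MB) echoes
in thousands of frames, localizing each to subwavelength precision, and
accumulating the positions into a density map. The central practical
difficulty is MB concentration: dilute bubbles are easy to localize but
saturate the vascular bed slowly, while clinically realistic concentrations
produce heavily overlapping echoes that defeat template-based localization.
`ulmloc` implements both sides of that trade-off: a conventional
normalized-cross-correlation localizer, and a U-Net regressor trained to
convert an ultrasound frame (envelope or RF) into a sharpened localization
map from which MB coordinates are read by blob detection. Everything needed
to study the methods — synthetic vessel masks, a frame simulator with ground
truth, the training loop, and the evaluation metrics — lives in the package.

## The synthetic data generator

The simulator emulates a high-frequency (20 MHz) linear-array system at the
conditions used throughout the package: speed of sound 1540 m/s, 4.9 µm
display pixels, wavelength λ = 77 µm, nine-angle plane-wave compounding
carried as metadata. Its model is a linear, shift-invariant superposition of
point responses:

* **PSF.** Each MB contributes an amplitude-scaled separable Gaussian
  envelope times a cosine carrier along depth at the pulse-echo spatial
  frequency `2 f0 / c` (about 26 cycles/mm, a 7.9-pixel period). The default
  widths are diffraction-limited values for an f-number ≈ 1 system at
  20 MHz: lateral FWHM of one wavelength (σ_lat = λ/2.355 ≈ 32.7 µm ≈ 6.7 px)
  and axial FWHM of half a wavelength (σ_ax ≈ 16.3 µm ≈ 3.3 px). These
  widths matter: they are what make conventional localization merge two
  tubes separated by 0.13 λ while still resolving 0.64 λ, the behaviour the
  resolution-phantom tests assert. Both σ are configurable in
  `sim_config()`.
* **Noise.** Per frame, a level is drawn uniformly in 10 % ± 2 % of the
  frame's peak amplitude and i.i.d. Gaussian noise of that standard
  deviation is added. The ± is read as variability across frames, so every
  training image sees a slightly different noise level.
* **Concentration.** High-concentration data draw the MB density from
  Normal(600, 600²) per mm², resampled below 1 MB/mm² (a left-truncated
  normal). Low-concentration (group 1) training data instead draw uniformly
  in (0, 300] MBs/mm². MB counts are `round(concentration × FOV area)`;
  positions are uniform over the field of view, or uniform over the vessel
  lumen (pixel draw plus subpixel jitter) when a mask is supplied. Echo
  amplitudes are uniform in [0.5, 1].
* **Representations.** RF frames are rendered directly; envelope (ENV)
  frames are the magnitude of the axial analytic signal of the *noisy* RF,
  so interference between overlapping bubbles is retained — the property
  that separates what an RF-input network can learn from what an ENV-input
  network can. IQ import is supported through `iq_to_rf()` (band-limited ×4
  axial interpolation plus remodulation) and `demodulate_rf()` its inverse.
* **Ground truth.** The localization target `y` is a one-hot map with a 1
  at the pixel nearest each MB (ties broken toward the smaller index).

What the generator deliberately does **not** model: nonlinear MB
oscillation, spatially varying PSFs, attenuation, tissue clutter, and flow
(frames in a sequence are independent placements). Passing tests therefore
demonstrate correctness of the algorithms under a clean linear image model,
not performance on in vivo data; tissue motion and clutter in particular are
only represented downstream by the SVD filter interface.

Vessel masks come either from `binarize_vessel_image()` — an adaptive
threshold against the Gaussian-weighted local mean, window 1/8 of the image
(odd), sensitivity 0.5, with a green-channel option for RGB input — or from
`generate_vessel_map()`, a correlated-random-walk generator with branching
that produces connected tubular structures with diameters spanning 3–9 px
(≈ 15–45 µm) by default, standing in for optical vessel imagery. The
two-tube resolution phantom (`two_tube_phantom()`, 5 px diameter, 2/6/10 px
gaps ≈ 0.13/0.38/0.64 λ) is generated exactly.

## The network and its loss

The regressor is a four-level U-Net: each encoder block is two
3×3 convolution – batch-norm – leaky-ReLU (slope 0.01) units followed by
2×2 max pooling (eight encoder convolutions in total), a two-convolution
bottleneck with dropout 0.5, and four decoder blocks that start with a 2×2
convolution halving the channel count, concatenate the spatially matching
encoder output, apply two conv–BN–activation units and upsample ×2 (eight
decoder convolutions); a two-convolution head produces the single-channel
map. Several architecture details are not pinned down by the problem and
were fixed as package defaults: base width 8 channels at desk scale
(32 reproduces a full-scale network), nearest-neighbour ×2 upsampling
(chosen over bilinear for its exact, simple adjoint — at these map sizes we
saw no benefit from bilinear), 3×3 kernels with unit padding, and He
initialization. RF-input and ENV-input networks share the 4.9 µm
localization grid: the simulator renders RF directly on that grid, where the
7.9-pixel pulse-echo carrier period is comfortably sampled, so no separate
dense input branch is needed (imported IQ data are brought toward display
resolution by `iq_to_rf()`'s ×4 band-limited axial interpolation). All of
it is configurable through `unet_spec()`. The layers
are implemented in the package (im2col + BLAS GEMM convolutions in C++ with
hand-derived backward passes); the test suite verifies every gradient
against numerical differentiation.

Training minimizes, with Adam at learning rate 0.001 and minibatches of 16,

L(m, y, ŷ) = α·MAE(G(y), ŷ) + (1 − SSIM(G(y), ŷ)) + β·FPLoss(m, LM(ŷ))

where G is a Gaussian blur with σ = 2 px of the one-hot target, α = 0.001,
and β = 1 exactly when the training samples carry vessel masks (0
otherwise). Readings that required a decision:

* **SSIM enters as a dissimilarity.** SSIM itself is maximal (1) for a
  perfect prediction, so the minimized term is 1 − SSIM; with that reading
  the loss is zero iff ŷ = G(y) when β = 0, which the tests assert.
* **Stabilizer pairing.** c₁ = (0.01 L)² goes with the mean term and
  c₂ = (0.03 L)² with the variance term, the standard SSIM form. Statistics
  are global (whole-map means, population variances and covariance).
* **Target scaling.** Targets are G(y) scaled by 2πσ² so an isolated MB
  peaks at 1; SSIM's dynamic range L is then 1. This is cosmetic (SSIM is
  invariant to a joint rescale with L, and α·MAE is negligible) but keeps
  the network output O(1).
* **FPLoss and gradients.** FPLoss is the fraction of predicted positives —
  strict regional maxima of ŷ above 10 % of the map maximum within a
  5×5 neighbourhood — that fall outside the vessel mask, defined as 0 when
  there are no positives. The local-maximum operator is not differentiable;
  the peak indicator is treated as a constant and the gradient flows through
  the predicted heights at the peak pixels (forward value remains the exact
  binary ratio). Raising an out-of-vessel peak increases the loss; raising
  an in-vessel peak decreases it.
* **MAE** divides by the number of pixels.

The desk-scale training protocol used by the tests and the acceptance
script is 200 vessel-constrained training images and 20 validation images at
64 × 64 px, base 8 channels, 20 epochs; it runs in a few minutes on one CPU,
reduces validation loss by well over 30 %, and the resulting RF-input model
resolves the 6-px (0.38 λ) two-tube phantom and out-localizes the
conventional method at 400 MBs/mm². The validation loss is evaluated before
training (epoch 0) and after each epoch, and the best-validation checkpoint
is retained. All randomness (initialization, shuffling, dropout, data
generation) derives from explicit seeds; identical configurations reproduce
identical loss curves bit for bit.

## Conventional localization

`localize_conventional()` follows the classical template route: a
zero-normalized cross-correlation map against a unit-peak Gaussian PSF
template, strict regional maxima above a correlation threshold, greedy
suppression to a minimum mutual distance, and an intensity-weighted centroid
refinement in a ±⌈σ⌉ window. Since the reference settings for this family
of methods are not fixed anywhere, the defaults were chosen to reproduce the
qualitative behaviour expected of the method — single-bubble error well
under half a pixel, merging of structures closer than ~0.13 λ, resolution of
0.64 λ: correlation threshold 0.5, minimum separation 2·mean(σ) px, and an
amplitude floor of 5 % of the frame maximum at accepted peaks. The floor is
needed because normalized correlation is scale-invariant and would otherwise
fire on arbitrarily faint smooth tails; being relative to the frame maximum,
it preserves the invariance of the detection set under global rescaling,
which the tests check.

DL-side coordinates are read off the enhanced map with difference-of-
Gaussian blob detection (`dog_localize()`): a geometric sigma ladder from 1
to 4 px in 5 steps, scale-normalized differences, 3-D (space × scale) local
maxima above 10 % of the stack maximum, and centroid refinement within the
blob radius.

## Evaluation conventions

* **Pairing** is a globally optimal one-to-one assignment minimizing total
  Euclidean distance (Hungarian algorithm via `clue`); pairs farther than
  `tol` (default 5 px = 0.32 λ) are broken into one false negative plus one
  false positive. A greedy nearest-neighbour mode exists for sensitivity
  analysis. The test suite checks optimality against exhaustive permutation
  enumeration on every instance with up to six points.
* **Rates.** FDR = FP/(FP+TP), miss rate = FN/(FN+TP), mean localization
  error = mean distance over true-positive pairs. Zero denominators return
  0 with an explicit `degenerate` flag rather than NaN.
* **Breakpoint.** The concentration at which a method stops localizing
  individual MBs is the first swept concentration whose mean miss rate
  exceeds 0.5 (no interpolation; `Inf` when never exceeded).
* **Vessel-domain metrics** classify each pixel by inside/outside the mask
  × localized/not; saturation time is the first frame at which the
  cumulative union of localized vessel pixels reaches the target fraction,
  divided by the frame rate, with localizations rounded to the nearest pixel
  (ties toward the smaller index).
* **Resolution phantoms** are scored on the density profile averaged along
  the tube direction: Gaussian smoothing with σ = 1.5 px (about the
  single-bubble localization uncertainty, so the count is insensitive to
  per-bin accumulation noise), then strict local maxima with height ≥ 30 %
  and prominence ≥ 25 % of the profile maximum — the latter close to the
  ~26 % intensity dip of two point sources at the Rayleigh limit. Two tubes
  count as resolved when exactly two such peaks appear.
* The **phantom and vessel test sequences** use 400 MBs/mm² (≈ 2.4 MBs/λ²),
  matching the average concentration regime of vessel-structured test data,
  over 200 frames.

## Pipeline numerics

The SVD clutter filter operates on the Casorati matrix (pixels × time) and
retains singular components `low_cutoff:high_cutoff` (1-based; the default
removes only the largest component). Simulated sequences skip the filter by
default since the simulator has no tissue signal. Density accumulation is
raw (no pairing or tracking): each localization increments its nearest
pixel, so counts are conserved exactly. The sliding-window display maintains
a running sum (add newest, subtract oldest), which is algebraically
identical to direct summation — asserted exactly in the tests. The
real-time pixel budget `⌊T / (t_DL + n_angles · t_BF)⌋` with the measured
costs 2.38 µs/px inference and 40 ns/px/angle beamforming reproduces the
printed reference values (36496 px at 10 Hz; 27.4 ms for a 100×100 frame).

Envelope detection and demodulation use the FFT analytic-signal
construction. On finite frames with a carrier that is not commensurate with
the frame length this has edge leakage, which is why the IQ↔RF round-trip
property is asserted on a commensurate grid (110 rows hold exactly 14
carrier cycles) where band-limitation holds exactly; an optional mirror
extension (`analytic_signal(mirror = TRUE)`) is available to tame edges on
real, long traces.

## Known limitations

Desk-scale networks are small and trained on hundreds, not thousands, of
images; their absolute metrics are not comparable to a full-scale training
run, and only orderings and qualitative behaviours (sharpening, resolution,
miss-rate advantage at high concentration) are asserted. The Gaussian PSF
is spatially invariant, so robustness to aberration and depth-dependent blur
is untested. Frames are temporally independent; methods that exploit MB
motion (tracking, temporal networks) are out of scope. The CLI and file
formats (TIFF/PNG masks, CSV localizations, JSON reports) cover the
simulation studies; clutter filtering is the only step intended for
user-supplied in vivo stacks.
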