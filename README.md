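# ulmloc — microbubble localization for ultrasound localization microscopy

Ultrasound localization microscopy (ULM) builds super-resolved maps of
microvasculature by localizing individual microbubble (MB) echoes across
thousands of ultrasound frames and accumulating the positions. Its accuracy
is limited by MB concentration: dilute bubbles localize well but cover the
vascular bed slowly, while realistic (high) concentrations overlap within
the point spread function (PSF) and defeat template-based localization.
`ulmloc` is a toolkit for studying that trade-off on fully synthetic data
with exact ground truth. It is aimed at researchers developing or evaluating
MB localization methods.

The package provides, end to end:

* **Synthetic data** — procedural or image-derived binary vessel masks;
  simulated RF / IQ / envelope frames of MB fields at controlled
  concentrations (uniform up to 300 MBs/mm², or drawn from a truncated
  Normal(600, 600²) per mm² for the high-concentration regime), with a
  separable Gaussian-envelope, cosine-carrier PSF at the pulse-echo spatial
  frequency 2·f0/c, per-frame Gaussian noise at 10 % ± 2 % of peak, and
  one-hot ground-truth localization maps.
* **Conventional localization** — zero-normalized cross-correlation against
  a synthesized Gaussian PSF template, thresholded regional maxima with
  non-maximum suppression, and subpixel intensity-weighted centroids.
* **Deep-learning localization** — a four-level U-Net (8 encoder + 8
  decoder convolutions, batch norm, leaky ReLU slope 0.01, bottleneck
  dropout), trained with Adam (learning rate 0.001, minibatches of 16) on
  the composite loss

  `L(m, y, ŷ) = α·MAE(G(y), ŷ) + (1 − SSIM(G(y), ŷ)) + β·FPLoss(m, LM(ŷ))`

  where `G` is a σ = 2 px Gaussian blur of the one-hot target, α = 0.001,
  and β = 1 when vessel masks `m` accompany the training data; `FPLoss` is
  the fraction of predicted peaks (local-maximum binarization `LM`) falling
  outside the vessels. The network and its backpropagation are implemented
  in the package (Rcpp/Armadillo convolutions), with every gradient checked
  numerically in the tests. MB coordinates are read off the sharpened
  network output by difference-of-Gaussian blob detection.
* **Evaluation** — globally optimal assignment pairing of detections to
  ground truth at tolerance `tol` (default 5 px = 0.32 λ); FDR = FP/(FP+TP),
  miss rate = FN/(FN+TP), mean localization error over paired detections;
  concentration sweeps and the 50 %-miss-rate breakpoint; two-tube
  resolution phantoms (0.13 / 0.38 / 0.64 λ separations); vessel-pixel
  confusion metrics; vessel saturation time; SVD clutter filtering; density
  accumulation; sliding-window high-resolution display; and the real-time
  pixel-budget arithmetic (36 496 px at 10 Hz for 2.38 µs/px inference plus
  9 × 40 ns/px beamforming).

## Worked example

Resolve the two-tube phantom (5-px tubes, 10-px ≈ 0.64 λ gap) with
conventional localization at a high concentration:

```r
library(ulmloc)
grid <- acoustic_grid(64, 64)        # 64 x 64 px at 4.9 um, 20 MHz
cfg  <- sim_config(grid = grid)      # PSF + 10% +/- 2% noise defaults

wavelength(grid) * 1e6                        # 77 (um)
signif(concentration_to_per_lambda2(400, grid), 2)   # 2.4 (MBs per lambda^2)

phantom <- two_tube_phantom(grid, diameter_px = 5, separation_px = 10)
frames  <- simulate_sequence(phantom, n_frames = 200, concentration = 400,
                             config = cfg, seed = 1)
res <- run_ulm(frames, "conventional", cfg)

round(colMeans(res$metrics[, -1]), 3)
#>        fdr  miss_rate mean_error
#>      0.001      0.917      0.000
count_profile_peaks(density_profile(res$density))
#> [1] 2
round(mean(res$metrics$mean_error) / 4.9e-6, 2)
#> [1] 1.35
```

At 400 MBs/mm² the conventional localizer misses most overlapping bubbles
(miss rate 0.92) but what it does localize is accurate (mean error 1.35 px,
FDR ≈ 0) and the accumulated density profile shows two resolved peaks at
the 0.64 λ separation. Shrink `separation_px` to 2 (0.13 λ) and the two
tubes merge into a single profile peak. A U-Net trained at desk scale —
`build_training_set(group = 3, ...)` followed by `train_unet()` (about five
minutes on one CPU) — recovers more of the missed bubbles
(`run_ulm(frames, "dl", cfg, model = model)`) and keeps the tubes separated
down to 6 px; see the methods vignette (`vignettes/ulm-methods.Rmd`) for
the full protocol and design rationale.

A thin command-line front end is included:

```sh
Rscript inst/cli/ulm.R units
Rscript inst/cli/ulm.R phantom --separation 6 --frames 200 --seed 1 --out density.csv
```

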