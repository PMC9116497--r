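#' Simulation configuration
#'
#' Collects every knob of the synthetic microbubble (MB) frame generator:
#' the acoustic grid, the point-spread-function (PSF) model, the per-frame
#' noise level, the concentration model used for high-concentration training
#' data, and the MB amplitude range.
#'
#' The PSF is a separable Gaussian envelope with a cosine carrier along the
#' axial axis at the pulse-echo spatial frequency 2 f0 / c. Default widths
#' correspond to a diffraction-limited system at the grid's frequency:
#' lateral full width at half maximum of one wavelength
#' (sigma_lateral = lambda / 2.355) and axial full width at half maximum of
#' half a wavelength (sigma_axial = lambda / 4.71), i.e. about 32.7 um and
#' 16.3 um at 20 MHz.
#'
#' @param grid An \code{\link{acoustic_grid}} (default 203 x 203 at 4.9 um,
#'   20 MHz).
#' @param noise_level_mean Mean additive white-noise level as a fraction of
#'   the signal peak (default 0.10).
#' @param noise_level_half_range Half-range of the per-frame uniform draw of
#'   the noise level (default 0.02, i.e. 10 percent plus or minus 2).
#' @param conc_mean,conc_sd Mean and SD (MBs/mm^2) of the normal
#'   concentration model used for high-concentration data (defaults 600 and
#'   600, truncated below at 1 by resampling).
#' @param sigma_lateral,sigma_axial Gaussian PSF widths in meters.
#' @param rf_carrier_spatial_freq Axial carrier spatial frequency in
#'   cycles/m; default 2 * f0 / c (pulse-echo).
#' @param amplitude_range Range of uniform MB echo amplitudes (default
#'   c(0.5, 1)).
#' @param n_compounding_angles Number of plane-wave compounding angles,
#'   carried as metadata for the real-time budget (default 9).
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(grid = acoustic_grid(),
                       noise_level_mean = 0.10,
                       noise_level_half_range = 0.02,
                       conc_mean = 600, conc_sd = 600,
                       sigma_lateral = wavelength(grid) / (2 * sqrt(2 * log(2))),
                       sigma_axial = sigma_lateral / 2,
                       rf_carrier_spatial_freq =
                         2 * grid$center_frequency / grid$speed_of_sound,
                       amplitude_range = c(0.5, 1),
                       n_compounding_angles = 9L) {
  stopifnot(inherits(grid, "acoustic_grid"))
  if (noise_level_mean < 0 || noise_level_mean > 1 ||
      noise_level_half_range < 0 || noise_level_half_range > 1) {
    stop("noise levels must be fractions in [0, 1]")
  }
  if (sigma_lateral <= 0 || sigma_axial <= 0) stop("PSF sigmas must be > 0")
  if (conc_mean < 0 || conc_sd < 0) stop("concentration model must be >= 0")
  structure(list(grid = grid,
                 noise_level_mean = noise_level_mean,
                 noise_level_half_range = noise_level_half_range,
                 conc_mean = conc_mean, conc_sd = conc_sd,
                 sigma_lateral = sigma_lateral, sigma_axial = sigma_axial,
                 rf_carrier_spatial_freq = rf_carrier_spatial_freq,
                 amplitude_range = amplitude_range,
                 n_compounding_angles = as.integer(n_compounding_angles)),
            class = "sim_config")
}

#' Microbubble field (ground truth)
#'
#' Continuous MB positions and echo amplitudes for one frame.
#'
#' @param positions n x 2 matrix of (axial, lateral) positions in meters.
#' @param amplitudes Positive echo amplitudes, length n.
#' @param frame_index Integer frame label.
#' @return An object of class \code{mb_field}.
#' @export
mb_field <- function(positions, amplitudes = rep(1, nrow(positions)),
                     frame_index = 0L) {
  if (!is.matrix(positions)) positions <- matrix(positions, ncol = 2)
  if (nrow(positions) != length(amplitudes)) {
    stop("one amplitude per position required")
  }
  if (length(amplitudes) && any(amplitudes <= 0)) {
    stop("amplitudes must be positive")
  }
  structure(list(positions = positions, amplitudes = as.numeric(amplitudes),
                 frame_index = as.integer(frame_index)),
            class = "mb_field")
}

#' @export
print.mb_field <- function(x, ...) {
  cat(sprintf("<mb_field> %d microbubbles (frame %d)\n",
              nrow(x$positions), x$frame_index))
  invisible(x)
}

#' Ultrasound frame
#'
#' One 2-D beamformed image with its grid metadata. \code{representation} is
#' \code{"RF"} (real, carrier-bearing), \code{"IQ"} (complex baseband) or
#' \code{"ENV"} (non-negative envelope).
#'
#' @param data Numeric (RF/ENV) or complex (IQ) matrix; rows are axial.
#' @param representation One of "RF", "IQ", "ENV".
#' @param grid An \code{\link{acoustic_grid}} consistent with \code{data}.
#' @param noise_level_applied Fraction of peak used when noise was added
#'   (0 if none).
#' @param carrier_spatial_freq Axial carrier spatial frequency in cycles/m
#'   (required to demodulate/remodulate RF and IQ).
#' @return An object of class \code{ulm_frame}.
#' @export
ulm_frame <- function(data, representation = c("RF", "IQ", "ENV"), grid,
                      noise_level_applied = 0, carrier_spatial_freq = NULL) {
  representation <- match.arg(representation)
  stopifnot(inherits(grid, "acoustic_grid"))
  if (nrow(data) != grid$n_rows || ncol(data) != grid$n_cols) {
    stop("frame dimensions must match the grid")
  }
  if (representation == "IQ" && !is.complex(data)) {
    stop("IQ frames must be complex")
  }
  if (representation != "IQ" && is.complex(data)) {
    stop("RF/ENV frames must be real-valued")
  }
  if (representation == "ENV" && any(data < 0)) {
    stop("ENV frames must be non-negative")
  }
  structure(list(data = data, representation = representation, grid = grid,
                 noise_level_applied = noise_level_applied,
                 carrier_spatial_freq = carrier_spatial_freq),
            class = "ulm_frame")
}

#' @export
print.ulm_frame <- function(x, ...) {
  cat(sprintf("<ulm_frame> %s %d x %d px, noise level %.3g\n",
              x$representation, nrow(x$data), ncol(x$data),
              x$noise_level_applied))
  invisible(x)
}

#' Draw a microbubble concentration from the high-concentration model
#'
#' One draw from Normal(conc_mean, conc_sd^2), resampled until the draw is
#' at least 1 MB/mm^2 (a left-truncated normal).
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Integer seed or NULL.
#' @return Concentration in MBs/mm^2.
#' @export
sample_concentration <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    if (config$conc_sd == 0) return(max(config$conc_mean, 1))
    repeat {
      x <- stats::rnorm(1, config$conc_mean, config$conc_sd)
      if (x >= 1) return(x)
    }
  })
}

#' Place microbubbles in the field of view
#'
#' Draws \code{round(concentration * FOV area)} MBs. Without a mask the
#' (axial, lateral) coordinates are uniform over the field of view. With a
#' \code{\link{vessel_mask}}, a vessel pixel is drawn uniformly and uniform
#' subpixel jitter added, so positions are uniform over the lumen. Amplitudes
#' are uniform in \code{config$amplitude_range}.
#'
#' @param concentration MBs per mm^2 (non-negative).
#' @param config A \code{\link{sim_config}}.
#' @param mask Optional \code{\link{vessel_mask}} constraining placement;
#'   its grid must match \code{config$grid}.
#' @param seed Integer seed or NULL.
#' @param frame_index Frame label for the returned field.
#' @return An \code{\link{mb_field}}.
#' @export
place_mbs <- function(concentration, config, mask = NULL, seed = NULL,
                      frame_index = 0L) {
  stopifnot(inherits(config, "sim_config"))
  if (concentration < 0) stop("concentration must be non-negative")
  grid <- config$grid
  n <- round(concentration * fov_area_mm2(grid))
  pa <- grid$pixel_size_axial; pl <- grid$pixel_size_lateral
  if (n == 0L) {
    return(mb_field(matrix(numeric(0), 0, 2), numeric(0), frame_index))
  }
  with_seed(seed, {
    if (is.null(mask)) {
      ax <- (stats::runif(n, -0.5, grid$n_rows - 0.5)) * pa
      lat <- (stats::runif(n, -0.5, grid$n_cols - 0.5)) * pl
    } else {
      stopifnot(inherits(mask, "vessel_mask"))
      idx <- which(mask$mask == 1L)
      if (length(idx) == 0L) stop("vessel mask has no vessel pixels")
      pick <- idx[sample.int(length(idx), n, replace = TRUE)]
      row0 <- (pick - 1L) %% nrow(mask$mask)        # 0-based row
      col0 <- (pick - 1L) %/% nrow(mask$mask)       # 0-based col
      ax <- (row0 + stats::runif(n, -0.5, 0.5)) * pa
      lat <- (col0 + stats::runif(n, -0.5, 0.5)) * pl
    }
    amp <- stats::runif(n, config$amplitude_range[1], config$amplitude_range[2])
    mb_field(cbind(ax, lat), amp, frame_index)
  })
}

#' Render the RF frame of a microbubble field
#'
#' Superposes, for each MB, an amplitude-scaled separable Gaussian envelope
#' multiplied by a cosine carrier along the axial axis:
#' \deqn{a \exp(-(z-z_0)^2/2\sigma_a^2 - (x-x_0)^2/2\sigma_l^2)
#'       \cos(2\pi k (z - z_0))}
#' with k the pulse-echo carrier spatial frequency. The model is linear and
#' shift-invariant; it stands in for a full acoustic simulation while
#' preserving the amplitude-plus-phase structure that distinguishes RF from
#' envelope data.
#'
#' @param field An \code{\link{mb_field}}.
#' @param config A \code{\link{sim_config}}.
#' @return An RF \code{\link{ulm_frame}}.
#' @export
render_rf <- function(field, config) {
  .render(field, config, carrier = TRUE)
}

#' Render the ideal (carrier-free) envelope image of a field
#'
#' The same Gaussian superposition as \code{\link{render_rf}} without the
#' carrier: the magnitude image an ideal envelope detector would produce for
#' non-interfering echoes. Mostly useful as a reference; simulated ENV data
#' should normally be produced by \code{\link{envelope_detect}} on RF so that
#' interference between overlapping MBs is retained.
#'
#' @inheritParams render_rf
#' @return An ENV \code{\link{ulm_frame}}.
#' @export
render_envelope_ideal <- function(field, config) {
  .render(field, config, carrier = FALSE)
}

.render <- function(field, config, carrier) {
  stopifnot(inherits(field, "mb_field"), inherits(config, "sim_config"))
  grid <- config$grid
  z <- (seq_len(grid$n_rows) - 1) * grid$pixel_size_axial
  x <- (seq_len(grid$n_cols) - 1) * grid$pixel_size_lateral
  img <- matrix(0, grid$n_rows, grid$n_cols)
  n <- nrow(field$positions)
  if (n > 0L) {
    for (i in seq_len(n)) {
      dz <- z - field$positions[i, 1]
      vz <- exp(-dz^2 / (2 * config$sigma_axial^2))
      if (carrier) vz <- vz * cos(2 * pi * config$rf_carrier_spatial_freq * dz)
      vx <- exp(-(x - field$positions[i, 2])^2 / (2 * config$sigma_lateral^2))
      img <- img + field$amplitudes[i] * (vz %o% vx)
    }
  }
  ulm_frame(img, if (carrier) "RF" else "ENV", grid,
            carrier_spatial_freq =
              if (carrier) config$rf_carrier_spatial_freq else NULL)
}

# Analytic signal along the axial (row) dimension, column by column, via
# the FFT (the standard hilbert construction). With mirror = TRUE the signal
# is even-extended first, which trades exactness on periodic inputs for
# reduced leakage at the frame borders on non-periodic ones.
analytic_signal <- function(mat, mirror = FALSE) {
  n0 <- nrow(mat)
  if (n0 < 2L) return(mat + 0i)
  x <- if (mirror) rbind(mat, mat[n0:1, , drop = FALSE]) else mat
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  F <- stats::mvfft(x)
  a <- stats::mvfft(F * h, inverse = TRUE) / n
  a[seq_len(n0), , drop = FALSE]
}

#' Envelope detection of an RF frame
#'
#' Magnitude of the axial analytic signal (Hilbert transform along the axial
#' dimension, applied per image column).
#'
#' @param frame An RF \code{\link{ulm_frame}}.
#' @return An ENV \code{\link{ulm_frame}} on the same grid.
#' @export
envelope_detect <- function(frame) {
  stopifnot(inherits(frame, "ulm_frame"))
  if (frame$representation != "RF") stop("envelope_detect expects an RF frame")
  env <- Mod(analytic_signal(frame$data))
  ulm_frame(env, "ENV", frame$grid, frame$noise_level_applied)
}

#' Add Gaussian white noise at a fraction of the signal peak
#'
#' The per-frame noise level is drawn uniformly in
#' \code{noise_level_mean +/- noise_level_half_range}; the noise standard
#' deviation is that level times the frame's peak absolute amplitude.
#' For an all-zero frame the peak is taken as 1.0 and the frame is flagged
#' with a warning.
#'
#' @param frame A real-valued \code{\link{ulm_frame}} (RF or ENV; ENV output
#'   is clipped at 0 to preserve non-negativity).
#' @param config A \code{\link{sim_config}}.
#' @param seed Integer seed or NULL.
#' @return The noisy frame with \code{noise_level_applied} recorded.
#' @export
add_noise <- function(frame, config, seed = NULL) {
  stopifnot(inherits(frame, "ulm_frame"), inherits(config, "sim_config"))
  if (!all(is.finite(frame$data))) stop("frame must be finite")
  if (config$noise_level_mean == 0 && config$noise_level_half_range == 0) {
    return(frame)
  }
  with_seed(seed, {
    level <- stats::runif(1,
                          config$noise_level_mean - config$noise_level_half_range,
                          config$noise_level_mean + config$noise_level_half_range)
    level <- max(level, 0)
    peak <- max(abs(frame$data))
    if (peak == 0) {
      warning("all-zero frame: noise level defined relative to 1.0")
      peak <- 1
    }
    noisy <- frame$data +
      matrix(stats::rnorm(length(frame$data), 0, level * peak),
             nrow(frame$data), ncol(frame$data))
    if (frame$representation == "ENV") noisy <- pmax(noisy, 0)
    ulm_frame(noisy, frame$representation, frame$grid,
              noise_level_applied = level,
              carrier_spatial_freq = frame$carrier_spatial_freq)
  })
}

# FFT-based band-limited interpolation along rows of a complex matrix.
fft_upsample_rows <- function(mat, factor) {
  n <- nrow(mat); m <- n * factor
  F <- stats::mvfft(mat)
  G <- matrix(0 + 0i, m, ncol(mat))
  if (n %% 2 == 0) {
    half <- n / 2
    G[1:half, ] <- F[1:half, ]
    # split the Nyquist bin between the positive and negative edges
    G[half + 1, ] <- F[half + 1, ] / 2
    G[m - half + 1, ] <- F[half + 1, ] / 2
    if (half >= 2) G[(m - half + 2):m, ] <- F[(half + 2):n, ]
  } else {
    half <- (n + 1) / 2
    G[1:half, ] <- F[1:half, ]
    G[(m - half + 2):m, ] <- F[(half + 1):n, ]
  }
  stats::mvfft(G, inverse = TRUE) / n
}

#' Convert a complex IQ frame to RF
#'
#' The axial dimension is band-limited upsampled by \code{factor} (default
#' 4) and the baseband signal remodulated onto the carrier:
#' \code{RF(z) = 2 Re(IQ(z) exp(+i 2 pi k z))}. The returned grid has
#' \code{factor} times the rows at a quarter of the axial pixel size, so
#' \code{\link{demodulate_rf}} inverts the operation up to band limitation.
#'
#' @param frame An IQ \code{\link{ulm_frame}} with
#'   \code{carrier_spatial_freq} set.
#' @param factor Integer axial upsampling factor (default 4).
#' @return An RF \code{\link{ulm_frame}} on the denser axial grid.
#' @export
iq_to_rf <- function(frame, factor = 4L) {
  stopifnot(inherits(frame, "ulm_frame"))
  if (frame$representation != "IQ") stop("iq_to_rf expects an IQ frame")
  if (is.null(frame$carrier_spatial_freq)) {
    stop("IQ frame is missing carrier_spatial_freq metadata")
  }
  g <- frame$grid
  iq_up <- fft_upsample_rows(frame$data, factor)
  z <- (seq_len(nrow(iq_up)) - 1) * g$pixel_size_axial / factor
  rf <- 2 * Re(iq_up * exp(2i * pi * frame$carrier_spatial_freq * z))
  grid_up <- acoustic_grid(n_rows = g$n_rows * factor, n_cols = g$n_cols,
                           pixel_size_axial = g$pixel_size_axial / factor,
                           pixel_size_lateral = g$pixel_size_lateral,
                           speed_of_sound = g$speed_of_sound,
                           center_frequency = g$center_frequency,
                           sampling_frequency = g$sampling_frequency)
  ulm_frame(rf, "RF", grid_up, frame$noise_level_applied,
            carrier_spatial_freq = frame$carrier_spatial_freq)
}

#' Demodulate an RF frame to complex baseband IQ
#'
#' Takes the axial analytic signal, mixes it down by the carrier and
#' decimates the axial dimension by \code{factor}.
#'
#' @param frame An RF \code{\link{ulm_frame}} with carrier metadata.
#' @param factor Integer axial decimation factor (default 4).
#' @return An IQ \code{\link{ulm_frame}}.
#' @export
demodulate_rf <- function(frame, factor = 4L) {
  stopifnot(inherits(frame, "ulm_frame"))
  if (frame$representation != "RF") stop("demodulate_rf expects an RF frame")
  if (is.null(frame$carrier_spatial_freq)) {
    stop("RF frame is missing carrier_spatial_freq metadata")
  }
  g <- frame$grid
  if (g$n_rows %% factor != 0) stop("n_rows must be divisible by factor")
  z <- (seq_len(g$n_rows) - 1) * g$pixel_size_axial
  # analytic signal of 2 Re(IQ e^{+i theta}) is 2 IQ e^{+i theta}
  base <- analytic_signal(frame$data) / 2 *
    exp(-2i * pi * frame$carrier_spatial_freq * z)
  keep <- seq(1L, g$n_rows, by = factor)
  grid_dn <- acoustic_grid(n_rows = length(keep), n_cols = g$n_cols,
                           pixel_size_axial = g$pixel_size_axial * factor,
                           pixel_size_lateral = g$pixel_size_lateral,
                           speed_of_sound = g$speed_of_sound,
                           center_frequency = g$center_frequency,
                           sampling_frequency = g$sampling_frequency)
  ulm_frame(base[keep, , drop = FALSE], "IQ", grid_dn,
            frame$noise_level_applied,
            carrier_spatial_freq = frame$carrier_spatial_freq)
}

#' Binary localization map of a microbubble field
#'
#' One-hot ground-truth map: 1 at the pixel nearest each MB (ties broken
#' toward the smaller index), 0 elsewhere.
#'
#' @param field An \code{\link{mb_field}}.
#' @param grid An \code{\link{acoustic_grid}}.
#' @return Integer matrix of 0/1.
#' @export
truth_map <- function(field, grid) {
  stopifnot(inherits(field, "mb_field"), inherits(grid, "acoustic_grid"))
  y <- matrix(0L, grid$n_rows, grid$n_cols)
  n <- nrow(field$positions)
  if (n == 0L) return(y)
  r <- ceiling(field$positions[, 1] / grid$pixel_size_axial - 0.5)
  c <- ceiling(field$positions[, 2] / grid$pixel_size_lateral - 0.5)
  r <- pmin(pmax(r, 0L), grid$n_rows - 1L)
  c <- pmin(pmax(c, 0L), grid$n_cols - 1L)
  y[cbind(r + 1L, c + 1L)] <- 1L
  y
}

#' Generate a training set of simulated microbubble frames
#'
#' Three regimes mirror the training-data groups used for network training:
#' group 1 draws concentrations uniformly in (0, 300] MBs/mm^2 with uniform
#' MB placement (low concentration); group 2 draws concentrations from the
#' truncated Normal(600, 600^2) model, still uniformly placed; group 3 uses
#' the same concentration model but places MBs inside a vessel mask, which is
#' retained with the sample so the false-positive loss can use it. Each
#' sample carries the noisy RF frame, the matching ENV frame (envelope of the
#' noisy RF), the binary localization map and the generating field.
#'
#' @param group 1, 2 or 3.
#' @param n_images Number of samples.
#' @param config A \code{\link{sim_config}} (its grid sets the frame size).
#' @param seed Integer seed; the data set is deterministic given
#'   (group, n_images, config, seed).
#' @param masks For group 3: a list of \code{\link{vessel_mask}} objects to
#'   cycle through, or NULL to generate a fresh procedural mask per sample.
#' @param vessel_params Parameters passed to
#'   \code{\link{generate_vessel_map}} when masks are generated.
#' @return List of samples, each a list with elements \code{frame_rf},
#'   \code{frame_env}, \code{truth}, \code{field}, \code{mask} (NULL for
#'   groups 1-2), \code{concentration}.
#' @export
build_training_set <- function(group, n_images, config, seed = 1L,
                               masks = NULL,
                               vessel_params = list(n_trunks = 3L,
                                                    branch_prob = 0.03,
                                                    diameter_range_px = c(3, 9),
                                                    meander = 0.2)) {
  stopifnot(group %in% 1:3, n_images >= 1, inherits(config, "sim_config"))
  lapply(seq_len(n_images), function(i) {
    s <- child_seed(seed, i)
    conc <- if (group == 1L) {
      with_seed(child_seed(s, 1L), stats::runif(1, 0, 300))
    } else {
      sample_concentration(config, child_seed(s, 1L))
    }
    mask <- NULL
    if (group == 3L) {
      mask <- if (!is.null(masks)) {
        masks[[(i - 1L) %% length(masks) + 1L]]
      } else {
        do.call(generate_vessel_map,
                c(list(seed = child_seed(s, 2L), grid = config$grid),
                  vessel_params))
      }
    }
    field <- place_mbs(conc, config, mask = mask, seed = child_seed(s, 3L))
    rf <- add_noise(render_rf(field, config), config, seed = child_seed(s, 4L))
    env <- envelope_detect(rf)
    list(frame_rf = rf, frame_env = env,
         truth = truth_map(field, config$grid), field = field,
         mask = mask, concentration = conc)
  })
}

#' Simulate a frame sequence with independent microbubble placements
#'
#' Each frame draws a fresh MB field at the given concentration inside the
#' mask (no flow model), renders RF, adds noise and keeps the ground truth.
#'
#' @param mask A \code{\link{vessel_mask}} (or NULL for full-FOV placement).
#' @param n_frames Number of frames (0 returns an empty list).
#' @param concentration MBs per mm^2.
#' @param config A \code{\link{sim_config}}.
#' @param seed Integer seed.
#' @return List of per-frame lists with \code{frame_rf}, \code{frame_env},
#'   \code{field}.
#' @export
simulate_sequence <- function(mask, n_frames, concentration, config,
                              seed = 1L) {
  stopifnot(n_frames >= 0, inherits(config, "sim_config"))
  lapply(seq_len(n_frames), function(t) {
    s <- child_seed(seed, t)
    field <- place_mbs(concentration, config, mask = mask,
                       seed = child_seed(s, 1L), frame_index = t - 1L)
    rf <- add_noise(render_rf(field, config), config, seed = child_seed(s, 2L))
    list(frame_rf = rf, frame_env = envelope_detect(rf), field = field)
  })
}
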