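# Grid with an exactly 1 mm x 1 mm field of view (200 px at 5 um).
grid_1mm <- function() acoustic_grid(200L, 200L, pixel_size = 5e-6)

test_that("concentration draws follow the truncated normal model", {
  cfg0 <- sim_config(grid = grid64(), conc_sd = 0)
  expect_equal(sample_concentration(cfg0, 1), 600)

  cfg <- sim_config(grid = grid64())
  expect_equal(sample_concentration(cfg, 9), sample_concentration(cfg, 9))

  draws <- vapply(1:10000, function(s) sample_concentration(cfg, s),
                  numeric(1))
  expect_true(all(draws >= 1))
  # closed-form mean of N(600, 600^2) truncated below at 1
  alpha <- (1 - 600) / 600
  mu_trunc <- 600 + 600 * dnorm(alpha) / (1 - pnorm(alpha))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mu_trunc), 3 * se)
})

test_that("microbubble placement honors counts, bounds and masks", {
  cfg <- sim_config(grid = grid_1mm())
  expect_identical(nrow(place_mbs(0, cfg)$positions), 0L)
  f <- place_mbs(100, cfg, seed = 3)
  expect_identical(nrow(f$positions), 100L)
  expect_true(all(f$amplitudes >= 0.5 & f$amplitudes <= 1))
  expect_true(all(f$positions[, 1] >= -2.5e-6 &
                  f$positions[, 1] <= (200 - 0.5) * 5e-6))

  # vessel mode: every position rounds into the 1-dilated mask
  g <- grid64()
  cfgm <- sim_config(grid = g)
  mask <- two_tube_phantom(g, 5L, 10L)
  fv <- place_mbs(400, cfgm, mask = mask, seed = 4)
  r <- round(fv$positions[, 1] / g$pixel_size_axial) + 1
  dil_rows <- sort(unique(c(which(rowSums(mask$mask) > 0),
                            which(rowSums(mask$mask) > 0) + 1L,
                            which(rowSums(mask$mask) > 0) - 1L)))
  expect_true(all(r %in% dil_rows))
  empty_mask <- generate_vessel_map(1, g, n_trunks = 0L, allow_empty = TRUE)
  expect_error(place_mbs(10, cfgm, mask = empty_mask), "no vessel pixels")
})

test_that("RF rendering is linear and peaks at the microbubble", {
  cfg <- noiseless_config()
  g <- cfg$grid
  empty <- render_rf(mb_field(matrix(numeric(0), 0, 2)), cfg)
  expect_true(all(empty$data == 0))

  pos <- matrix(c(30.6, 33.2) * 4.9e-6, 1, 2)
  one <- render_rf(mb_field(pos), cfg)
  env <- envelope_detect(one)
  peak <- which(env$data == max(env$data), arr.ind = TRUE)
  expect_lte(abs(peak[1] - 1 - 30.6), 1)
  expect_lte(abs(peak[2] - 1 - 33.2), 1)

  # superposition: two-MB frame equals the sum of single-MB frames
  pos2 <- matrix(c(10.1, 45.3, 50.2, 12.8), 2, 2)
  f2 <- render_rf(mb_field(pos2 * 4.9e-6, c(0.7, 1)), cfg)
  fa <- render_rf(mb_field(pos2[1, , drop = FALSE] * 4.9e-6, 0.7), cfg)
  fb <- render_rf(mb_field(pos2[2, , drop = FALSE] * 4.9e-6, 1), cfg)
  expect_equal(f2$data, fa$data + fb$data, tolerance = 1e-12)
})

test_that("envelope detection recovers the analytic envelope", {
  cfg <- noiseless_config()
  zero <- ulm_frame(matrix(0, 64, 64), "RF", grid64())
  expect_true(all(envelope_detect(zero)$data == 0))

  # carrier * Gaussian along each column, several carrier phases
  z <- 0:63
  gz <- exp(-(z - 32)^2 / (2 * 6^2))
  k <- 1 / 8  # cycles per pixel, well below Nyquist
  for (phase in c(0, 0.7, 2.1)) {
    rf <- matrix(gz * cos(2 * pi * k * z + phase), 64, 5)
    env <- envelope_detect(ulm_frame(rf, "RF", acoustic_grid(64L, 5L)))
    interior <- 10:54
    rms <- sqrt(mean((env$data[interior, 1] - gz[interior])^2))
    expect_lt(rms, 0.02)
  }
  expect_error(envelope_detect(zero_env <- ulm_frame(matrix(0, 4, 4), "ENV",
                                                     acoustic_grid(4L, 4L))),
               "RF")
})

test_that("noise level tracks the configured fraction of peak", {
  g <- acoustic_grid(320L, 320L)
  cfg <- sim_config(grid = g, noise_level_mean = 0.1,
                    noise_level_half_range = 0)
  base <- ulm_frame(matrix(0, 320, 320), "RF", g)
  base$data[160, 160] <- 1  # peak 1
  noisy <- add_noise(base, cfg, seed = 8)
  resid <- noisy$data - base$data
  expect_lt(abs(sd(resid) - 0.10), 0.005)
  expect_equal(noisy$noise_level_applied, 0.1)

  quiet <- sim_config(grid = g, noise_level_mean = 0,
                      noise_level_half_range = 0)
  expect_identical(add_noise(base, quiet, seed = 1)$data, base$data)

  n1 <- add_noise(base, cfg, seed = 1)
  n2 <- add_noise(base, cfg, seed = 2)
  expect_false(identical(n1$data, n2$data))

  allzero <- ulm_frame(matrix(0, 320, 320), "RF", g)
  expect_warning(add_noise(allzero, cfg, seed = 1), "all-zero")
})

test_that("IQ to RF conversion remodulates correctly and round-trips", {
  # 110 rows x 4.9 um hold exactly 14 pulse-echo carrier cycles, so the
  # band-limitation assumptions of the FFT-based transforms hold exactly
  n <- 110L
  g <- acoustic_grid(n, 8L)
  cfg <- sim_config(grid = g)
  k <- cfg$rf_carrier_spatial_freq
  expect_equal(k * g$pixel_size_axial * n, 14)

  zero_iq <- ulm_frame(matrix(0 + 0i, n, 8), "IQ", g,
                       carrier_spatial_freq = k)
  expect_true(all(iq_to_rf(zero_iq)$data == 0))

  # constant-amplitude IQ -> RF is a sampled cosine of the carrier
  const_iq <- ulm_frame(matrix(0.5 + 0i, n, 8), "IQ", g,
                        carrier_spatial_freq = k)
  rf <- iq_to_rf(const_iq)
  z <- (seq_len(nrow(rf$data)) - 1) * rf$grid$pixel_size_axial
  expected <- 2 * 0.5 * cos(2 * pi * k * z)
  expect_lt(max(abs(rf$data[, 1] - expected)), 1e-10)

  # round trip on random band-limited IQ: random spectrum confined to
  # frequencies well below the carrier (so the sidebands do not overlap)
  set.seed(5)
  spec <- matrix(0 + 0i, n, 8)
  lowbins <- c(1:6, (n - 4):n)  # |f| <= 6/110 cycles/px << carrier 0.127
  spec[lowbins, ] <- complex(real = rnorm(length(lowbins) * 8),
                             imaginary = rnorm(length(lowbins) * 8))
  smooth <- stats::mvfft(spec, inverse = TRUE) / n
  iq <- ulm_frame(smooth, "IQ", g, carrier_spatial_freq = k)
  back <- demodulate_rf(iq_to_rf(iq))
  rel <- sqrt(mean(Mod(back$data - iq$data)^2)) /
    sqrt(mean(Mod(iq$data)^2))
  expect_lt(rel, 0.02)

  no_carrier <- ulm_frame(matrix(0 + 0i, n, 8), "IQ", g)
  expect_error(iq_to_rf(no_carrier), "carrier")
})

test_that("truth maps are one-hot at the nearest pixel with low-index ties", {
  g <- grid64()
  f <- mb_field(matrix(c(10.4, 20.6) * 4.9e-6, 1, 2))
  y <- truth_map(f, g)
  expect_identical(sum(y), 1L)
  expect_identical(which(y == 1, arr.ind = TRUE)[1, ],
                   c(row = 10L + 1L, col = 21L + 1L))
  # exactly half-way between pixels 5 and 6 -> smaller index wins
  tie <- mb_field(matrix(c(5.5, 5.5) * 4.9e-6, 1, 2))
  yt <- truth_map(tie, g)
  expect_identical(which(yt == 1, arr.ind = TRUE)[1, ],
                   c(row = 6L, col = 6L))
})

test_that("training-set groups follow their concentration and mask rules", {
  cfg <- sim_config(grid = grid64())
  g1 <- build_training_set(1, 8, cfg, seed = 21)
  expect_true(all(vapply(g1, `[[`, numeric(1), "concentration") <= 300))
  expect_true(all(vapply(g1, function(s) is.null(s$mask), logical(1))))

  g3 <- build_training_set(3, 4, cfg, seed = 22)
  expect_true(all(vapply(g3, function(s) !is.null(s$mask) &&
                           sum(s$mask$mask) > 0, logical(1))))
  expect_true(all(vapply(g3, function(s)
    all(s$frame_env$data >= 0), logical(1))))

  a <- build_training_set(2, 3, cfg, seed = 33)
  b <- build_training_set(2, 3, cfg, seed = 33)
  expect_identical(a, b)
})

test_that("simulated sequences stay inside the vessel and cover it", {
  cfg <- noiseless_config()
  g <- cfg$grid
  ph <- two_tube_phantom(g, 5L, 10L)
  expect_identical(simulate_sequence(ph, 0, 400, cfg), list())
  seqd <- simulate_sequence(ph, 200, 400, cfg, seed = 12)
  expect_length(seqd, 200L)
  tube_rows <- which(rowSums(ph$mask) > 0)
  covered <- matrix(FALSE, g$n_rows, g$n_cols)
  for (fr in seqd) {
    p <- fr$field$positions
    r <- round(p[, 1] / g$pixel_size_axial) + 1
    expect_true(all(r >= min(tube_rows) - 1 & r <= max(tube_rows) + 1))
    rr <- pmin(pmax(round(p[, 1] / g$pixel_size_axial) + 1, 1), g$n_rows)
    cc <- pmin(pmax(round(p[, 2] / g$pixel_size_lateral) + 1, 1), g$n_cols)
    covered[cbind(rr, cc)] <- TRUE
  }
  coverage <- sum(covered & ph$mask == 1) / sum(ph$mask)
  expect_gte(coverage, 0.9)
})
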