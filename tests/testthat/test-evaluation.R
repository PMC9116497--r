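test_that("pairing matches exhaustive enumeration on small instances", {
  set.seed(99)
  for (trial in 1:500) {
    nt <- sample(0:6, 1); np <- sample(0:6, 1)
    truth <- matrix(runif(2 * nt), ncol = 2)
    pred <- matrix(runif(2 * np), ncol = 2)
    tol <- runif(1, 0.1, 0.8)
    got <- pair_detections(truth, pred, tol)
    expect_identical(got$tp + got$fn, nt)
    expect_identical(got$tp + got$fp, np)
    if (nt > 0 && np > 0) {
      ora <- oracle_assignment(truth, pred, tol)
      # same minimal total distance implies an equivalent assignment
      sol_cost <- sum(sqrt(rowSums((truth[got$pairs$truth_index, ,
                                          drop = FALSE] -
                                    pred[got$pairs$pred_index, ,
                                         drop = FALSE])^2)))
      expect_identical(got$tp, ora$tp)
    }
  }
})

test_that("pairing boundary cases and crossing configurations", {
  pts <- matrix(c(0.1, 0.1, 0.5, 0.5, 0.9, 0.1), 3, 2, byrow = TRUE)
  same <- pair_detections(pts, pts, tol = 0.01)
  expect_identical(same$tp, 3L)
  expect_equal(same$pairs$distance, rep(0, 3))

  none <- pair_detections(pts, matrix(numeric(0), 0, 2), tol = 0.1)
  expect_identical(none$fn, 3L)
  expect_identical(none$fp, 0L)
  expect_identical(none$tp, 0L)

  # crossing configuration where greedy and optimal differ in cost
  truth <- rbind(c(0, 0), c(0, 1), c(0, 2.2))
  pred <- rbind(c(0, 0.9), c(0, 1.9), c(0, 3.0))
  opt <- pair_detections(truth, pred, tol = 1)
  ora <- oracle_assignment(truth, pred, 1)
  expect_identical(opt$tp, ora$tp)
  expect_error(pair_detections(truth, pred, tol = 0), "positive")
})

test_that("detection metrics reproduce hand-computed values", {
  # FP = 1, TP = 3 -> FDR 0.25; distances 1 and 3 px -> mean 2 px
  truth <- rbind(c(0, 0), c(0, 10), c(0, 20)) * 1e-6
  pred <- rbind(c(0, 1), c(0, 13), c(0, 20), c(50, 50)) * 1e-6
  pr <- pair_detections(truth, pred, tol = 5e-6)
  met <- detection_metrics(pr)
  expect_equal(met$fdr, 0.25)
  expect_equal(met$miss_rate, 0)
  expect_equal(met$mean_error, mean(c(1, 3, 0)) * 1e-6)  # paired distances
  expect_false(met$degenerate)

  empty <- detection_metrics(pair_detections(matrix(numeric(0), 0, 2),
                                             matrix(numeric(0), 0, 2),
                                             tol = 1))
  expect_true(empty$degenerate)
  expect_equal(empty$fdr, 0)
})

test_that("breakpoint extraction follows the first-exceedance rule", {
  curve <- data.frame(concentration = c(100, 200, 300),
                      miss_rate = c(0.2, 0.4, 0.6))
  expect_equal(breakpoint_concentration(curve), 300)
  low <- data.frame(concentration = c(100, 200), miss_rate = c(0.1, 0.2))
  expect_identical(breakpoint_concentration(low), Inf)
  expect_error(breakpoint_concentration(curve[0, ]), "empty")
})

test_that("vessel-pixel metrics equal exhaustive pixel classification", {
  g <- acoustic_grid(4L, 4L)
  m <- vessel_mask(matrix(c(1, 1, 0, 0,
                            1, 1, 0, 0,
                            0, 0, 0, 0,
                            0, 0, 0, 1), 4, 4, byrow = TRUE), g)
  density <- matrix(c(2, 0, 1, 0,
                      0, 1, 0, 0,
                      0, 0, 0, 0,
                      0, 0, 0, 0), 4, 4, byrow = TRUE)
  vm <- vessel_pixel_metrics(m, density)
  # by hand: vessel = 5 px, hits = 4 px; TP = {11,22}, FP = {13},
  # FN = {12,21,44}, TN = 10
  expect_identical(c(vm$tp, vm$fp, vm$fn, vm$tn), c(2L, 1L, 3L, 10L))
  expect_equal(vm$vessel_fdr, 1 / 3)
  expect_equal(vm$vessel_miss_rate, 3 / 5)

  full <- vessel_pixel_metrics(m, m$mask + 0)
  expect_equal(full$vessel_fdr, 0)
  expect_equal(full$vessel_miss_rate, 0)

  inverted <- vessel_pixel_metrics(m, 1 - m$mask)
  expect_equal(inverted$vessel_fdr, 1)
  expect_equal(inverted$vessel_miss_rate, 1)
})

test_that("saturation time follows the constructed coverage schedule", {
  g <- acoustic_grid(10L, 10L)
  mask <- vessel_mask(matrix(1L, 10, 10), g)
  px <- g$pixel_size_axial
  # frame t localizes exactly one new vessel pixel (1% per frame, disjoint)
  locs <- lapply(1:100, function(t) {
    r <- (t - 1) %% 10; c <- (t - 1) %/% 10
    localization_set(matrix(c(r, c) * px, 1, 2), 1, t - 1L)
  })
  sat <- saturation_time(mask, locs, frame_rate = 100)
  expect_identical(sat$frames_needed, 90L)
  expect_equal(sat$time, 0.9)

  # full coverage from the first frame at 1000 Hz
  all_px <- as.matrix(expand.grid(0:9, 0:9)) * px
  one <- list(localization_set(all_px, rep(1, 100)))
  expect_equal(saturation_time(mask, one, 1000)$time, 0.001)

  never <- saturation_time(mask, locs[1:10], 100)
  expect_identical(never$time, Inf)
  expect_error(saturation_time(vessel_mask(matrix(0L, 10, 10), g), locs, 100),
               "no vessel")
})

test_that("sweeps are reproducible and degrade with concentration", {
  cfg <- noiseless_config()
  sig <- psf_sigma_px(cfg)
  localizer <- function(s) localize_conventional(s$frame_env, sig)
  cc <- c(5, 300)
  sw1 <- concentration_sweep(localizer, cc, cfg, n_reps = 3, seed = 2)
  sw2 <- concentration_sweep(localizer, cc, cfg, n_reps = 3, seed = 2)
  expect_identical(sw1, sw2)
  expect_lt(sw1$miss_rate[1], sw1$miss_rate[2])
  one <- concentration_sweep(localizer, 50, cfg, n_reps = 1, seed = 3)
  expect_identical(one$miss_rate_sd, 0)
})
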