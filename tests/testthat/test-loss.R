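test_that("leaky ReLU matches its closed form", {
  expect_equal(leaky_relu(2), 2)
  expect_equal(leaky_relu(-2), -0.02)
  expect_equal(leaky_relu(0), 0)
  x <- matrix(c(-3, -0.5, 0, 0.5, 3, -1), 2, 3)
  expect_equal(leaky_relu(x), ifelse(x > 0, x, 0.01 * x))
})

test_that("target blurring matches a sampled Gaussian and conserves mass", {
  z <- matrix(0L, 33, 33)
  expect_true(all(blur_target(z) == 0))
  z[17, 17] <- 1L
  got <- blur_target(z, 2)
  # analytic separable kernel oracle
  k1 <- exp(-(-8:8)^2 / (2 * 4)); k1 <- k1 / sum(k1)
  ref <- outer(k1, k1)
  expect_lt(max(abs(got[9:25, 9:25] - ref)), 1e-6)
  expect_lt(abs(sum(got) - 1), 0.01)
  expect_error(blur_target(matrix(0.5, 3, 3)), "binary")
})

test_that("mae, ssim, fp_loss and lm_binarize agree with brute force on random maps", {
  set.seed(42)
  for (trial in 1:200) {
    a <- matrix(runif(64), 8, 8)
    b <- matrix(runif(64), 8, 8)
    m <- matrix(rbinom(64, 1, 0.5), 8, 8)
    yb <- lm_binarize(b, 1L, 0.05)
    expect_lt(abs(mae(a, b) - oracle_mae(a, b)), 1e-10)
    expect_lt(abs(ssim(a, b) - oracle_ssim(a, b)), 1e-10)
    expect_identical(yb, oracle_lm(b, 1L, 0.05))
    expect_lt(abs(fp_loss(m, yb) - oracle_fp(m, yb)), 1e-10)
  }
})

test_that("ssim satisfies its boundary cases", {
  a <- matrix(runif(64), 8, 8)
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim(matrix(c(0, 1, 0, 1), 2), matrix(c(1, 0, 1, 0), 2)),
               oracle_ssim(matrix(c(0, 1, 0, 1), 2),
                           matrix(c(1, 0, 1, 0), 2)))
  expect_error(ssim(a, matrix(0, 2, 2)), "shape")
  # stabilizers at L = 1
  expect_equal((0.01 * 1)^2, 1e-4)
  expect_equal((0.03 * 1)^2, 9e-4)
})

test_that("lm_binarize handles flat and spiked maps", {
  expect_true(all(lm_binarize(matrix(1, 9, 9)) == 0L))
  spike <- matrix(0, 9, 9); spike[5, 5] <- 2
  got <- lm_binarize(spike)
  expect_identical(sum(got), 1L)
  expect_identical(got[5, 5], 1L)
})

test_that("fp_loss boundary behavior", {
  m <- matrix(0L, 4, 4); m[, 1:2] <- 1L
  inside <- matrix(0L, 4, 4); inside[2, 1] <- 1L; inside[3, 2] <- 1L
  expect_equal(fp_loss(m, inside), 0)
  outside <- matrix(0L, 4, 4); outside[2, 4] <- 1L
  expect_equal(fp_loss(m, outside), 1)
  mixed <- matrix(0L, 4, 4)
  mixed[1, 1] <- 1L; mixed[2, 2] <- 1L; mixed[3, 1] <- 1L; mixed[4, 4] <- 1L
  expect_equal(fp_loss(m, mixed), 0.25)
  expect_equal(fp_loss(m, matrix(0L, 4, 4)), 0)
})

test_that("total loss composes its three terms and vanishes at the target", {
  set.seed(7)
  y <- matrix(0L, 16, 16); y[c(40, 130, 200)] <- 1L
  cfg <- loss_config(alpha = 0.001, beta = 0)
  g <- blur_target(y, cfg$blur_sigma)
  at_target <- total_loss(y, g, cfg)
  expect_equal(at_target$loss, 0, tolerance = 1e-12)

  # alpha = 0, beta = 0 isolates the SSIM dissimilarity
  yh <- matrix(runif(256), 16, 16)
  iso <- total_loss(y, yh, loss_config(alpha = 0, beta = 0))
  expect_equal(iso$loss, 1 - ssim(g, yh, 1))

  # handcrafted 8 x 8 case: sum of independently computed terms
  y8 <- matrix(0L, 8, 8); y8[3, 3] <- 1L; y8[6, 7] <- 1L
  m8 <- matrix(0L, 8, 8); m8[, 1:4] <- 1L
  yh8 <- matrix(runif(64), 8, 8)
  cfg8 <- loss_config(alpha = 0.5, beta = 2, lm_neighborhood = 1L,
                      lm_min_height = 0.05)
  g8 <- blur_target(y8, cfg8$blur_sigma)
  expected <- 0.5 * oracle_mae(g8, yh8) + (1 - oracle_ssim(g8, yh8)) +
    2 * oracle_fp(m8, oracle_lm(yh8, 1L, 0.05))
  expect_equal(total_loss(y8, yh8, cfg8, m = m8)$loss, expected,
               tolerance = 1e-12)
  expect_error(total_loss(y8, yh8, loss_config(beta = 1)), "mask")
})

test_that("loss gradient matches numerical differentiation (beta = 0)", {
  set.seed(11)
  y <- matrix(0L, 8, 8); y[2, 5] <- 1L; y[7, 3] <- 1L
  yh <- matrix(runif(64, 0.1, 1), 8, 8)
  cfg <- loss_config(alpha = 0.05, beta = 0)
  res <- total_loss(y, yh, cfg, with_grad = TRUE)
  eps <- 1e-7
  for (idx in c(1, 10, 28, 37, 64)) {
    yp <- yh; yp[idx] <- yp[idx] + eps
    ym <- yh; ym[idx] <- ym[idx] - eps
    num <- (total_loss(y, yp, cfg)$loss - total_loss(y, ym, cfg)$loss) /
      (2 * eps)
    expect_lt(abs(res$grad[idx] - num), 1e-5)
  }
})

test_that("false-positive surrogate gradient acts only at detected peaks", {
  # the binary local-max map is gradient-constant; the surrogate routes the
  # gradient through the predicted heights at the peak pixels
  set.seed(12)
  y <- matrix(0L, 8, 8); y[4, 4] <- 1L
  m <- matrix(0L, 8, 8); m[, 1:4] <- 1L
  yh <- matrix(runif(64, 0.05, 0.3), 8, 8)
  yh[3, 2] <- 1; yh[6, 7] <- 0.9  # one peak inside, one outside the mask
  cfg <- loss_config(alpha = 0, beta = 1, lm_neighborhood = 1L,
                     lm_min_height = 0.5)
  lm <- lm_binarize(yh, 1L, 0.5)
  expect_identical(sum(lm), 2L)
  base <- total_loss(y, yh, loss_config(alpha = 0, beta = 0),
                     with_grad = TRUE)
  full <- total_loss(y, yh, cfg, m = m, with_grad = TRUE)
  extra <- full$grad - base$grad
  expect_true(all(extra[lm == 0L] == 0))
  denom <- sum(lm * yh); num <- sum((1 - m) * lm * yh)
  expect_equal(extra[3, 2], ((1 - m[3, 2]) * denom - num) / denom^2)
  expect_equal(extra[6, 7], ((1 - m[6, 7]) * denom - num) / denom^2)
  # raising the outside peak increases the loss, raising the inside one
  # decreases it
  expect_gt(extra[6, 7], 0)
  expect_lt(extra[3, 2], 0)
})
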