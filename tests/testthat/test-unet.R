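test_that("network backpropagation matches numerical gradients", {
  set.seed(1)
  spec <- unet_spec(base_channels = 2L, n_levels = 2L, dropout = 0)
  params <- ulmloc:::unet_init(spec, seed = 3)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 1, 2))
  tgt <- list(matrix(runif(256), 16), matrix(runif(256), 16))
  lc <- loss_config(alpha = 0.01, beta = 0)
  loss_of <- function(p) {
    fw <- ulmloc:::unet_forward(p, x, spec, training = TRUE)
    ulmloc:::batch_loss_and_grad(fw$y, tgt, list(NULL, NULL), lc,
                                 with_grad = FALSE)$loss
  }
  fw <- ulmloc:::unet_forward(params, x, spec, training = TRUE)
  bl <- ulmloc:::batch_loss_and_grad(fw$y, tgt, list(NULL, NULL), lc)
  bw <- ulmloc:::unet_backward(fw$params, fw, bl$dy, spec)
  eps <- 1e-6
  probes <- list(
    list(\(p) p$enc[[1]]$conv1$w[1, 1, 1, 1],
         \(p, v) { p$enc[[1]]$conv1$w[1, 1, 1, 1] <- v; p },
         \(g) g$enc[[1]]$conv1$w[1, 1, 1, 1]),
    list(\(p) p$enc[[2]]$conv2$gamma[2],
         \(p, v) { p$enc[[2]]$conv2$gamma[2] <- v; p },
         \(g) g$enc[[2]]$conv2$gamma[2]),
    list(\(p) p$bott$conv1$w[2, 3, 1, 4],
         \(p, v) { p$bott$conv1$w[2, 3, 1, 4] <- v; p },
         \(g) g$bott$conv1$w[2, 3, 1, 4]),
    list(\(p) p$dec[[1]]$halve$w[1, 2, 3, 2],
         \(p, v) { p$dec[[1]]$halve$w[1, 2, 3, 2] <- v; p },
         \(g) g$dec[[1]]$halve$w[1, 2, 3, 2]),
    list(\(p) p$dec[[2]]$conv2$beta[1],
         \(p, v) { p$dec[[2]]$conv2$beta[1] <- v; p },
         \(g) g$dec[[2]]$conv2$beta[1]),
    list(\(p) p$out$conv2$w[2, 2, 1, 1],
         \(p, v) { p$out$conv2$w[2, 2, 1, 1] <- v; p },
         \(g) g$out$conv2$w[2, 2, 1, 1]))
  for (pr in probes) {
    p0 <- pr[[1]](params)
    num <- (loss_of(pr[[2]](params, p0 + eps)) -
            loss_of(pr[[2]](params, p0 - eps))) / (2 * eps)
    ana <- pr[[3]](bw$grads)
    expect_lt(abs(ana - num), 1e-6 + 1e-4 * abs(num))
  }
})

test_that("architecture bookkeeping: output grid and channel halving", {
  spec <- unet_spec(base_channels = 4L, n_levels = 3L, dropout = 0)
  params <- ulmloc:::unet_init(spec, seed = 1)
  # 2x2 decoder convs halve channel counts exactly
  for (l in seq_len(3)) {
    d <- dim(params$dec[[l]]$halve$w)
    expect_identical(d[4], d[3] %/% 2L)
  }
  x <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  fw <- ulmloc:::unet_forward(params, x, spec)
  expect_identical(dim(fw$y), c(32L, 32L, 1L, 1L))
  # eight convolution layers per path at the default depth
  def <- unet_spec()
  expect_identical(def$n_levels * 2L, 8L)
})

test_that("a short training run records losses and reproduces exactly", {
  cfg <- sim_config(grid = acoustic_grid(32L, 32L))
  ds <- suppressWarnings(build_training_set(1, 24, cfg, seed = 5))
  spec <- unet_spec(base_channels = 4L, representation = "ENV")
  tc <- train_config(epochs = 2L, batch_size = 8L, seed = 3L)
  m1 <- train_unet(ds[1:16], ds[17:24], spec, loss_config(beta = 0), tc)
  expect_identical(nrow(m1$history), 3L)             # epoch 0 + 2 epochs
  expect_false(any(is.na(m1$history$val_loss)))
  expect_false(any(is.na(m1$history$train_loss[-1])))
  expect_true(all(m1$history$val_loss > 0))
  m2 <- train_unet(ds[1:16], ds[17:24], spec, loss_config(beta = 0), tc)
  expect_identical(m1$history, m2$history)           # fully seeded
  expect_identical(m1$params, m2$params)
})

test_that("enhancement produces a non-negative map of the input size", {
  cfg <- sim_config(grid = acoustic_grid(32L, 32L))
  ds <- suppressWarnings(build_training_set(1, 16, cfg, seed = 6))
  model <- train_unet(ds[1:12], ds[13:16],
                      unet_spec(base_channels = 4L, representation = "ENV"),
                      loss_config(beta = 0),
                      train_config(epochs = 1L, batch_size = 8L, seed = 2L))
  enh <- enhance_frame(model, ds[[1]]$frame_env)
  expect_identical(dim(enh), c(32L, 32L))
  expect_true(all(enh >= 0))
  expect_error(enhance_frame(model, ds[[1]]$frame_rf), "ENV")
})
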