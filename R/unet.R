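# U-Net localization-map regressor: a four-level encoder-decoder with two
# convolution-batchnorm-leakyReLU units per block (eight convolution layers
# on each path), dropout in the bottleneck, 2x2 channel-halving convolutions
# and nearest-neighbor x2 upsampling in the decoder, skip connections
# concatenated at matching spatial size, and a two-convolution output head.
# All layers are implemented in-package (conv kernels in src/convops.cpp);
# gradients are exact and verified against numerical differentiation in the
# test suite.

#' U-Net architecture specification
#'
#' @param base_channels Channels of the first encoder block; each deeper
#'   level doubles them (default 8 for desk-scale training; 32 reproduces a
#'   full-size network).
#' @param n_levels Number of encoder/decoder levels (default 4, i.e. eight
#'   convolution layers per path).
#' @param in_channels Input channels (1).
#' @param dropout Bottleneck dropout rate (default 0.5).
#' @param negative_slope Leaky ReLU slope (default 0.01).
#' @param representation Input representation the network is trained on,
#'   \code{"ENV"} or \code{"RF"}.
#' @return An object of class \code{unet_spec}.
#' @export
unet_spec <- function(base_channels = 8L, n_levels = 4L, in_channels = 1L,
                      dropout = 0.5, negative_slope = 0.01,
                      representation = c("ENV", "RF")) {
  representation <- match.arg(representation)
  structure(list(base_channels = as.integer(base_channels),
                 n_levels = as.integer(n_levels),
                 in_channels = as.integer(in_channels),
                 dropout = dropout, negative_slope = negative_slope,
                 representation = representation),
            class = "unet_spec")
}

# ---- parameter initialization --------------------------------------------

new_conv <- function(kh, kw, cin, cout, bn = TRUE) {
  w <- array(stats::rnorm(kh * kw * cin * cout) * sqrt(2 / (kh * kw * cin)),
             dim = c(kh, kw, cin, cout))
  p <- list(w = w, b = numeric(cout), bn = bn)
  if (bn) {
    p$gamma <- rep(1, cout); p$beta <- numeric(cout)
    p$rm <- numeric(cout); p$rv <- rep(1, cout)
  }
  p
}

#' Initialize U-Net parameters
#'
#' He-initialized convolution kernels, unit batch-norm scale, zero biases.
#'
#' @param spec A \code{\link{unet_spec}}.
#' @param seed Integer seed for reproducible initialization.
#' @return Parameter list (opaque; consumed by the trainer and
#'   \code{\link{enhance_frame}}).
#' @export
unet_init <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  with_seed(seed, {
    L <- spec$n_levels
    ch <- spec$base_channels * 2^(0:(L - 1))       # encoder channels
    cb <- ch[L] * 2L                               # bottleneck channels
    enc <- vector("list", L)
    cin <- spec$in_channels
    for (l in seq_len(L)) {
      enc[[l]] <- list(conv1 = new_conv(3, 3, cin, ch[l]),
                       conv2 = new_conv(3, 3, ch[l], ch[l]))
      cin <- ch[l]
    }
    bott <- list(conv1 = new_conv(3, 3, ch[L], cb),
                 conv2 = new_conv(3, 3, cb, cb))
    dec <- vector("list", L)
    cup <- cb
    for (l in seq_len(L)) {
      skip <- ch[L - l + 1L]
      half <- cup / 2L                             # 2x2 conv halves channels
      dec[[l]] <- list(halve = new_conv(2, 2, cup, half),
                       conv1 = new_conv(3, 3, half + skip, skip),
                       conv2 = new_conv(3, 3, skip, skip))
      cup <- skip
    }
    out <- list(conv1 = new_conv(3, 3, ch[1], ch[1]),
                conv2 = new_conv(3, 3, ch[1], 1, bn = FALSE))
    list(enc = enc, bott = bott, dec = dec, out = out)
  })
}

# ---- layer primitives (R side) -------------------------------------------

# Batch normalization over (H, W, N) per channel. Arrays are reshaped to
# (H*W) x (C*N) matrices, whose column c + C*(n-1) holds channel c of sample
# n, so per-channel statistics are row means of a C x N colMeans matrix.
bn_fw <- function(z, p, training, momentum = 0.9, eps = 1e-5) {
  d <- dim(z); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  zm <- matrix(z, HW, C * N)
  if (training) {
    mu <- rowMeans(matrix(.colMeans(zm, HW, C * N), C, N))
    v <- rowMeans(matrix(.colMeans(zm * zm, HW, C * N), C, N)) - mu^2
    p$rm <- momentum * p$rm + (1 - momentum) * mu
    p$rv <- momentum * p$rv + (1 - momentum) * v
  } else {
    mu <- p$rm; v <- p$rv
  }
  inv <- 1 / sqrt(v + eps)
  ecol <- function(v) rep(rep(v, N), each = HW)   # expand per-channel values
  xh <- (zm - ecol(mu)) * ecol(inv)
  out <- xh * ecol(p$gamma) + ecol(p$beta)
  dim(xh) <- c(HW, C * N)
  dim(out) <- d
  list(out = out, p = p, cache = list(xh = xh, inv = inv, d = d))
}

bn_bw <- function(dout, p, cache) {
  d <- cache$d; HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  dm <- matrix(dout, HW, C * N)
  xh <- cache$xh
  M <- HW * N
  csum <- function(m) rowSums(matrix(.colSums(m, HW, C * N), C, N))
  ecol <- function(v) rep(rep(v, N), each = HW)
  dgamma <- csum(dm * xh)
  dbeta <- csum(dm)
  dxh <- dm * ecol(p$gamma)
  dz <- (dxh - ecol(csum(dxh) / M) - xh * ecol(csum(dxh * xh) / M)) *
    ecol(cache$inv)
  dim(dz) <- d
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

# conv (+ optional BN) + leaky ReLU
cba_fw <- function(x, p, pads, slope, training) {
  z <- conv2d_fw(x, p$w, p$b, pads[1], pads[2], pads[3], pads[4])
  if (p$bn) {
    bn <- bn_fw(z, p, training)
    p <- bn$p
    a <- bn$out
    cache <- list(x = x, bn = bn$cache)
  } else {
    a <- z
    cache <- list(x = x)
  }
  pos <- a > 0
  out <- a * (pos + slope * !pos)
  dim(out) <- dim(a)
  cache$pos <- pos
  list(out = out, p = p, cache = cache)
}

cba_bw <- function(dout, p, cache, pads, slope) {
  da <- dout * (cache$pos + slope * !cache$pos)
  dim(da) <- dim(dout)
  if (p$bn) {
    bn <- bn_bw(da, p, cache$bn)
    dz <- bn$dz
  } else {
    dz <- da
  }
  g <- conv2d_bw(cache$x, p$w, dz, pads[1], pads[2], pads[3], pads[4])
  grads <- list(w = g$dw, b = g$db)
  if (p$bn) { grads$gamma <- bn$dgamma; grads$beta <- bn$dbeta }
  list(dx = g$dx, grads = grads)
}

mp_fw <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  o1 <- seq(1, H, 2); e1 <- o1 + 1; o2 <- seq(1, W, 2); e2 <- o2 + 1
  s1 <- x[o1, o2, , , drop = FALSE]; s2 <- x[e1, o2, , , drop = FALSE]
  s3 <- x[o1, e2, , , drop = FALSE]; s4 <- x[e1, e2, , , drop = FALSE]
  y <- pmax(s1, s2, s3, s4)
  m1 <- s1 == y; m2 <- (s2 == y) & !m1; m3 <- (s3 == y) & !m1 & !m2
  m4 <- !(m1 | m2 | m3)
  list(out = y, cache = list(m = list(m1, m2, m3, m4), d = d))
}

mp_bw <- function(dy, cache) {
  d <- cache$d; H <- d[1]; W <- d[2]
  o1 <- seq(1, H, 2); e1 <- o1 + 1; o2 <- seq(1, W, 2); e2 <- o2 + 1
  dx <- array(0, d)
  m <- cache$m
  dx[o1, o2, , ] <- dy * m[[1]]; dx[e1, o2, , ] <- dy * m[[2]]
  dx[o1, e2, , ] <- dy * m[[3]]; dx[e1, e2, , ] <- dy * m[[4]]
  dx
}

up_fw <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

up_bw <- function(dy) {
  d <- dim(dy); H <- d[1]; W <- d[2]
  o1 <- seq(1, H, 2); e1 <- o1 + 1; o2 <- seq(1, W, 2); e2 <- o2 + 1
  dy[o1, o2, , , drop = FALSE] + dy[e1, o2, , , drop = FALSE] +
    dy[o1, e2, , , drop = FALSE] + dy[e1, e2, , , drop = FALSE]
}

# ---- forward / backward over the whole network ---------------------------

PAD3 <- c(1L, 1L, 1L, 1L)  # 'same' for 3x3
PAD2 <- c(0L, 1L, 0L, 1L)  # 'same' for 2x2

#' @keywords internal
unet_forward <- function(params, x, spec, training = FALSE,
                         dropout_mask = NULL) {
  sl <- spec$negative_slope
  L <- spec$n_levels
  cache <- list(enc = vector("list", L), dec = vector("list", L))
  skips <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    c1 <- cba_fw(h, params$enc[[l]]$conv1, PAD3, sl, training)
    params$enc[[l]]$conv1 <- c1$p
    c2 <- cba_fw(c1$out, params$enc[[l]]$conv2, PAD3, sl, training)
    params$enc[[l]]$conv2 <- c2$p
    pool <- mp_fw(c2$out)
    skips[[l]] <- pool$out
    cache$enc[[l]] <- list(c1 = c1$cache, c2 = c2$cache, mp = pool$cache)
    h <- pool$out
  }
  b1 <- cba_fw(h, params$bott$conv1, PAD3, sl, training)
  params$bott$conv1 <- b1$p
  hb <- b1$out
  if (training && spec$dropout > 0) {
    if (is.null(dropout_mask)) {
      dropout_mask <- array(stats::runif(length(hb)) >= spec$dropout,
                            dim(hb)) / (1 - spec$dropout)
    }
    hb <- hb * dropout_mask
  }
  b2 <- cba_fw(hb, params$bott$conv2, PAD3, sl, training)
  params$bott$conv2 <- b2$p
  cache$bott <- list(c1 = b1$cache, c2 = b2$cache, mask = dropout_mask)
  h <- b2$out
  for (l in seq_len(L)) {
    hv <- cba_fw(h, params$dec[[l]]$halve, PAD2, sl, training)
    params$dec[[l]]$halve <- hv$p
    sk <- skips[[L - l + 1L]]
    d <- dim(hv$out); dc <- dim(sk)
    cat_in <- array(0, c(d[1], d[2], d[3] + dc[3], d[4]))
    cat_in[, , seq_len(d[3]), ] <- hv$out
    cat_in[, , d[3] + seq_len(dc[3]), ] <- sk
    c1 <- cba_fw(cat_in, params$dec[[l]]$conv1, PAD3, sl, training)
    params$dec[[l]]$conv1 <- c1$p
    c2 <- cba_fw(c1$out, params$dec[[l]]$conv2, PAD3, sl, training)
    params$dec[[l]]$conv2 <- c2$p
    h <- up_fw(c2$out)
    cache$dec[[l]] <- list(hv = hv$cache, c1 = c1$cache, c2 = c2$cache,
                           nch_up = d[3])
  }
  o1 <- cba_fw(h, params$out$conv1, PAD3, sl, training)
  params$out$conv1 <- o1$p
  z <- conv2d_fw(o1$out, params$out$conv2$w, params$out$conv2$b,
                 PAD3[1], PAD3[2], PAD3[3], PAD3[4])
  cache$out <- list(c1 = o1$cache, x2 = o1$out)
  list(y = z, cache = cache, params = params, skips_dims = lapply(skips, dim))
}

#' @keywords internal
unet_backward <- function(params, fw, dy, spec) {
  sl <- spec$negative_slope
  L <- spec$n_levels
  cache <- fw$cache
  grads <- list(enc = vector("list", L), dec = vector("list", L))
  g2 <- conv2d_bw(cache$out$x2, params$out$conv2$w, dy,
                  PAD3[1], PAD3[2], PAD3[3], PAD3[4])
  grads$out <- list(conv2 = list(w = g2$dw, b = g2$db))
  b1 <- cba_bw(g2$dx, params$out$conv1, cache$out$c1, PAD3, sl)
  grads$out$conv1 <- b1$grads
  dh <- b1$dx
  dskips <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dcu <- up_bw(dh)
    c2 <- cba_bw(dcu, params$dec[[l]]$conv2, cache$dec[[l]]$c2, PAD3, sl)
    c1 <- cba_bw(c2$dx, params$dec[[l]]$conv1, cache$dec[[l]]$c1, PAD3, sl)
    nu <- cache$dec[[l]]$nch_up
    dcat <- c1$dx
    dhv <- dcat[, , seq_len(nu), , drop = FALSE]
    dskips[[L - l + 1L]] <- dcat[, , -seq_len(nu), , drop = FALSE]
    hv <- cba_bw(dhv, params$dec[[l]]$halve, cache$dec[[l]]$hv, PAD2, sl)
    grads$dec[[l]] <- list(halve = hv$grads, conv1 = c1$grads,
                           conv2 = c2$grads)
    dh <- hv$dx
  }
  b2 <- cba_bw(dh, params$bott$conv2, cache$bott$c2, PAD3, sl)
  dhb <- b2$dx
  if (!is.null(cache$bott$mask)) dhb <- dhb * cache$bott$mask
  b1g <- cba_bw(dhb, params$bott$conv1, cache$bott$c1, PAD3, sl)
  grads$bott <- list(conv1 = b1g$grads, conv2 = b2$grads)
  dh <- b1g$dx
  for (l in rev(seq_len(L))) {
    dpool <- dh + dskips[[l]]
    dx2 <- mp_bw(dpool, cache$enc[[l]]$mp)
    c2 <- cba_bw(dx2, params$enc[[l]]$conv2, cache$enc[[l]]$c2, PAD3, sl)
    c1 <- cba_bw(c2$dx, params$enc[[l]]$conv1, cache$enc[[l]]$c1, PAD3, sl)
    grads$enc[[l]] <- list(conv1 = c1$grads, conv2 = c2$grads)
    dh <- c1$dx
  }
  list(grads = grads, dx = dh)
}

# ---- flat parameter traversal for the optimizer --------------------------

# Recursively walk params/grads in lockstep and apply f(value, grad, path).
walk_params <- function(params, grads, f, path = character()) {
  trainable <- c("w", "b", "gamma", "beta")
  nms <- names(params)
  for (k in seq_along(params)) {
    nm <- if (!is.null(nms) && nzchar(nms[k])) nms[k] else as.character(k)
    if (nm %in% c("bn", "rm", "rv")) next
    p <- params[[k]]
    g <- if (!is.null(nms) && nzchar(nms[k])) grads[[nm]] else grads[[k]]
    if (is.list(p)) {
      params[[k]] <- walk_params(p, g, f, c(path, nm))
    } else if (nm %in% trainable && !is.null(g)) {
      params[[k]] <- f(p, g, paste(c(path, nm), collapse = "/"))
    }
  }
  params
}

adam_state_env <- function() new.env(parent = emptyenv())

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk_params(params, grads, function(p, g, key) {
    m <- state[[paste0(key, ".m")]]
    v <- state[[paste0(key, ".v")]]
    if (is.null(m)) { m <- p * 0; v <- p * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    state[[paste0(key, ".m")]] <- m
    state[[paste0(key, ".v")]] <- v
    mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
    p - lr * mh / (sqrt(vh) + eps)
  })
}

# ---- training ------------------------------------------------------------

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Minibatch size (default 16).
#' @param epochs Number of epochs.
#' @param seed Integer seed covering initialization, shuffling and dropout.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 16L,
                         epochs = 20L, seed = 1L) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

# Build (input array, target list, mask list) from simulator samples.
prepare_batch_inputs <- function(samples, representation, gain, blur_sigma) {
  xs <- lapply(samples, function(s) {
    d <- if (representation == "RF") s$frame_rf$data else s$frame_env$data
    peak <- max(abs(d))
    if (peak > 0) d / peak else d
  })
  targets <- lapply(samples, function(s) blur_target(s$truth, blur_sigma) * gain)
  masks <- lapply(samples, function(s) if (is.null(s$mask)) NULL else s$mask$mask)
  H <- nrow(xs[[1]]); W <- ncol(xs[[1]])
  x <- array(0, c(H, W, 1L, length(xs)))
  for (i in seq_along(xs)) x[, , 1L, i] <- xs[[i]]
  list(x = x, targets = targets, masks = masks)
}

batch_loss_and_grad <- function(y, targets, masks, loss_cfg, with_grad = TRUE) {
  B <- dim(y)[4]
  dy <- if (with_grad) array(0, dim(y)) else NULL
  total <- 0
  for (b in seq_len(B)) {
    yb <- y[, , 1L, b]
    res <- total_loss(NULL, yb, loss_cfg, m = masks[[b]],
                      target = targets[[b]], with_grad = with_grad)
    total <- total + res$loss
    if (with_grad) dy[, , 1L, b] <- res$grad / B
  }
  list(loss = total / B, dy = dy)
}

#' Train the U-Net localization regressor
#'
#' Minimizes the composite loss over simulated samples with Adam, evaluating
#' the validation loss before training (epoch 0) and after every epoch; the
#' parameters with the best validation loss are retained. Fully seeded:
#' identical configurations yield identical loss curves.
#'
#' @param train_set,val_set Lists of samples from
#'   \code{\link{build_training_set}} (or \code{\link{simulate_sequence}}
#'   with truth maps added).
#' @param spec A \code{\link{unet_spec}}; its \code{representation} selects
#'   RF or ENV input.
#' @param loss_cfg A \code{\link{loss_config}}; set \code{beta = 1} when the
#'   samples carry vessel masks.
#' @param train_cfg A \code{\link{train_config}}.
#' @param target_gain Scale applied to the blurred target so an isolated
#'   microbubble peaks at 1 (default \code{2 pi blur_sigma^2}); keeps the
#'   SSIM dynamic range at 1.
#' @param verbose Print per-epoch losses.
#' @return An object of class \code{ulm_unet} with elements \code{params}
#'   (best validation checkpoint), \code{spec}, \code{loss_cfg},
#'   \code{train_cfg}, \code{history} (data.frame epoch/train_loss/val_loss,
#'   epoch 0 = untrained).
#' @export
train_unet <- function(train_set, val_set, spec = unet_spec(),
                       loss_cfg = loss_config(), train_cfg = train_config(),
                       target_gain = 2 * pi * loss_cfg$blur_sigma^2,
                       verbose = FALSE) {
  stopifnot(length(train_set) >= 1)
  if (loss_cfg$beta > 0 && is.null(train_set[[1]]$mask)) {
    stop("beta > 0 requires samples with vessel masks")
  }
  rep_ <- spec$representation
  params <- unet_init(spec, seed = train_cfg$seed)
  state <- adam_state_env()
  val_prep <- prepare_batch_inputs(val_set, rep_, target_gain,
                                   loss_cfg$blur_sigma)
  eval_val <- function(params) {
    n <- dim(val_prep$x)[4]
    total <- 0
    bs <- train_cfg$batch_size
    for (start in seq(1, n, by = bs)) {
      idx <- start:min(start + bs - 1L, n)
      fw <- unet_forward(params, val_prep$x[, , , idx, drop = FALSE], spec,
                         training = FALSE)
      bl <- batch_loss_and_grad(fw$y, val_prep$targets[idx],
                                val_prep$masks[idx], loss_cfg,
                                with_grad = FALSE)
      total <- total + bl$loss * length(idx)
    }
    total / n
  }
  history <- data.frame(epoch = 0L, train_loss = NA_real_,
                        val_loss = eval_val(params))
  best <- list(val = history$val_loss[1], params = params)
  tstep <- 0L
  with_seed(child_seed(train_cfg$seed, 99L), {
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample(length(train_set))
      ep_loss <- 0; nb <- 0
      for (start in seq(1, length(ord), by = train_cfg$batch_size)) {
        idx <- ord[start:min(start + train_cfg$batch_size - 1L, length(ord))]
        prep <- prepare_batch_inputs(train_set[idx], rep_, target_gain,
                                     loss_cfg$blur_sigma)
        fw <- unet_forward(params, prep$x, spec, training = TRUE)
        params <- fw$params          # running BN stats updated
        bl <- batch_loss_and_grad(fw$y, prep$targets, prep$masks, loss_cfg)
        bw <- unet_backward(params, fw, bl$dy, spec)
        tstep <- tstep + 1L
        params <- adam_step(params, bw$grads, state,
                            train_cfg$learning_rate, tstep)
        ep_loss <- ep_loss + bl$loss; nb <- nb + 1
      }
      vl <- eval_val(params)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                  val_loss = vl))
      if (vl < best$val) best <- list(val = vl, params = params)
      if (verbose) {
        message(sprintf("epoch %d: train %.4f, val %.4f",
                        epoch, ep_loss / nb, vl))
      }
    }
  })
  structure(list(params = best$params, spec = spec, loss_cfg = loss_cfg,
                 train_cfg = train_cfg, target_gain = target_gain,
                 history = history),
            class = "ulm_unet")
}

#' @export
print.ulm_unet <- function(x, ...) {
  cat(sprintf("<ulm_unet> %s input, base %d channels, %d levels\n",
              x$spec$representation, x$spec$base_channels, x$spec$n_levels))
  cat(sprintf("  best val loss %.4f over %d epochs\n",
              min(x$history$val_loss), max(x$history$epoch)))
  invisible(x)
}

#' Sharpen a frame with a trained network
#'
#' Runs inference on one frame (normalized by its peak absolute amplitude)
#' and returns the non-negative predicted localization map: the "sharpened"
#' microbubble image whose peaks mark MB positions.
#'
#' @param model A trained \code{\link{train_unet}} model.
#' @param frame An \code{\link{ulm_frame}} whose representation matches the
#'   model's.
#' @return Non-negative numeric matrix on the frame's grid.
#' @export
enhance_frame <- function(model, frame) {
  stopifnot(inherits(model, "ulm_unet"), inherits(frame, "ulm_frame"))
  if (frame$representation != model$spec$representation) {
    stop(sprintf("model expects %s input, frame is %s",
                 model$spec$representation, frame$representation))
  }
  d <- frame$data
  peak <- max(abs(d))
  if (peak > 0) d <- d / peak
  x <- array(d, c(nrow(d), ncol(d), 1L, 1L))
  fw <- unet_forward(model$params, x, model$spec, training = FALSE)
  pmax(fw$y[, , 1L, 1L], 0)
}
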