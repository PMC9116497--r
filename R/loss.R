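#' Leaky rectified linear unit
#'
#' Elementwise \code{x} for positive inputs and \code{0.01 x} otherwise.
#'
#' @param x Numeric scalar or array.
#' @param slope Negative-side slope (default 0.01).
#' @return Same shape as \code{x}.
#' @export
leaky_relu <- function(x, slope = 0.01) {
  ifelse(x > 0, x, slope * x)
}

#' Gaussian-blurred localization target
#'
#' Convolves a binary localization map with a Gaussian filter
#' (sigma = 2 pixels by default, reflective borders, unit-mass kernel). The
#' blurred map is the regression target the network output is compared to.
#'
#' @param y Binary matrix (the one-hot localization map).
#' @param blur_sigma Gaussian sigma in pixels (default 2).
#' @return Real-valued matrix of the same size.
#' @export
blur_target <- function(y, blur_sigma = 2) {
  if (!all(y %in% c(0, 1))) stop("y must be binary")
  gaussian_blur(y + 0, blur_sigma)
}

#' Mean absolute error between two maps
#'
#' @param a,b Numeric arrays of identical shape.
#' @return Mean over entries of \code{|a - b|}.
#' @export
mae <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  mean(abs(a - b))
}

#' Global structural similarity index
#'
#' SSIM computed from the global means, variances (population, i.e. 1/N
#' normalized) and covariance of the two maps:
#' \deqn{SSIM = \frac{(2\mu_a\mu_b + c_1)(2\sigma_{ab} + c_2)}
#'                   {(\mu_a^2+\mu_b^2+c_1)(\sigma_a^2+\sigma_b^2+c_2)}}
#' with stabilizers \code{c1 = (0.01 L)^2} and \code{c2 = (0.03 L)^2} where
#' L is the dynamic range.
#'
#' @param a,b Numeric arrays of identical shape.
#' @param L Dynamic range of the maps (default 1).
#' @return Scalar in [-1, 1]; 1 iff the maps are identical.
#' @export
ssim <- function(a, b, L = 1) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  if (L <= 0) stop("L must be positive")
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  n <- length(a)
  mu_a <- mean(a); mu_b <- mean(b)
  va <- sum((a - mu_a)^2) / n
  vb <- sum((b - mu_b)^2) / n
  cab <- sum((a - mu_a) * (b - mu_b)) / n
  ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
}

# Gradient of ssim(a, b, L) with respect to b (a held fixed).
ssim_grad_b <- function(a, b, L = 1) {
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  n <- length(a)
  mu_a <- mean(a); mu_b <- mean(b)
  va <- sum((a - mu_a)^2) / n
  vb <- sum((b - mu_b)^2) / n
  cab <- sum((a - mu_a) * (b - mu_b)) / n
  A1 <- 2 * mu_a * mu_b + c1; B1 <- mu_a^2 + mu_b^2 + c1
  A2 <- 2 * cab + c2;         B2 <- va + vb + c2
  # dS/db_i via quotient rule on S = A1 A2 / (B1 B2)
  dmu  <- 1 / n
  dcov <- (a - mu_a) / n
  dvb  <- 2 * (b - mu_b) / n
  num_d <- (2 * mu_a * dmu) * A2 * B1 * B2 + (2 * dcov) * A1 * B1 * B2 -
    A1 * A2 * ((2 * mu_b * dmu) * B2 + dvb * B1)
  num_d / (B1 * B2)^2
}

#' Binarize a predicted map by local-maximum filtering
#'
#' Marks with 1 exactly the strict regional maxima (within a square
#' neighborhood) whose height is at least \code{min_height} times the global
#' maximum; all other pixels are 0. A constant map has no strict maxima and
#' yields all zeros.
#'
#' @param y_hat Finite numeric matrix.
#' @param neighborhood Neighborhood radius in pixels (default 2, i.e. 5x5).
#' @param min_height Height threshold as a fraction of the map maximum
#'   (default 0.1).
#' @return Integer 0/1 matrix.
#' @export
lm_binarize <- function(y_hat, neighborhood = 2L, min_height = 0.1) {
  if (!all(is.finite(y_hat))) stop("map must be finite")
  peaks <- regional_maxima(y_hat, radius = as.integer(neighborhood))
  top <- max(y_hat)
  out <- (peaks & y_hat >= min_height * top) + 0L
  matrix(out, nrow(y_hat), ncol(y_hat))
}

#' False-positive loss
#'
#' Fraction of predicted positives that fall outside the vessel mask:
#' \code{sum((1 - m) * yhat_bin) / sum(yhat_bin)}. When there are no
#' positives the loss is defined as 0 (no positives, no false positives).
#'
#' @param m Binary vessel mask matrix.
#' @param y_hat_bin Binary predicted localization map (same shape).
#' @return Scalar in [0, 1].
#' @export
fp_loss <- function(m, y_hat_bin) {
  if (!identical(dim(m), dim(y_hat_bin))) stop("shape mismatch")
  if (!all(m %in% c(0, 1))) stop("mask must be binary")
  denom <- sum(y_hat_bin)
  if (denom == 0) return(0)
  sum((1 - m) * y_hat_bin) / denom
}

#' Loss configuration
#'
#' @param alpha Weight of the MAE term (default 0.001).
#' @param beta Weight of the false-positive term: 1 when training data carry
#'   vessel masks, 0 otherwise.
#' @param blur_sigma Gaussian sigma (pixels) of the target blur (default 2).
#' @param ssim_L Dynamic range used by the SSIM stabilizers (default 1; the
#'   trainer rescales targets so an isolated microbubble peaks at 1).
#' @param lm_neighborhood Local-maximum neighborhood radius (default 2).
#' @param lm_min_height Local-maximum height threshold as fraction of map
#'   max (default 0.1).
#' @return An object of class \code{loss_config}.
#' @export
loss_config <- function(alpha = 0.001, beta = 0, blur_sigma = 2,
                        ssim_L = 1, lm_neighborhood = 2L,
                        lm_min_height = 0.1) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be non-negative")
  if (blur_sigma <= 0) stop("blur_sigma must be positive")
  structure(list(alpha = alpha, beta = beta, blur_sigma = blur_sigma,
                 ssim_L = ssim_L, lm_neighborhood = as.integer(lm_neighborhood),
                 lm_min_height = lm_min_height),
            class = "loss_config")
}

#' Composite training loss
#'
#' \deqn{L(m, y, \hat y) = \alpha\,MAE(G(y), \hat y) +
#'       (1 - SSIM(G(y), \hat y)) + \beta\,FPLoss(m, LM(\hat y))}
#' where G is the Gaussian target blur and LM the local-maximum
#' binarization. SSIM enters as a dissimilarity (1 - SSIM) so that a perfect
#' prediction has zero loss; the local-maximum map is treated as
#' gradient-constant, with the false-positive term backpropagating through
#' the predicted values at the peak pixels.
#'
#' @param y Binary ground-truth localization map (or a pre-blurred target via
#'   \code{target}).
#' @param y_hat Predicted map, same shape.
#' @param config A \code{\link{loss_config}}.
#' @param m Binary vessel mask; required when \code{config$beta > 0}.
#' @param target Optional precomputed target (overrides blurring of y).
#' @param with_grad If TRUE, also return the gradient with respect to
#'   \code{y_hat}.
#' @return List with \code{loss} and the three components (\code{mae_term},
#'   \code{ssim_term}, \code{fp_term}); with \code{grad} when requested.
#' @export
total_loss <- function(y, y_hat, config = loss_config(), m = NULL,
                       target = NULL, with_grad = FALSE) {
  stopifnot(inherits(config, "loss_config"))
  if (config$beta > 0 && is.null(m)) {
    stop("beta > 0 requires a vessel mask")
  }
  g <- if (is.null(target)) blur_target(y, config$blur_sigma) else target
  if (!identical(dim(g), dim(y_hat))) stop("shape mismatch")
  mae_v <- mae(g, y_hat)
  ssim_v <- ssim(g, y_hat, config$ssim_L)
  lm <- lm_binarize(y_hat, config$lm_neighborhood, config$lm_min_height)
  fp_v <- if (config$beta > 0) fp_loss(m, lm) else 0
  loss <- config$alpha * mae_v + (1 - ssim_v) + config$beta * fp_v
  out <- list(loss = loss, mae_term = mae_v, ssim_term = ssim_v,
              fp_term = fp_v)
  if (with_grad) {
    grad <- config$alpha * sign(y_hat - g) / length(g) -
      ssim_grad_b(g, y_hat, config$ssim_L)
    if (config$beta > 0 && sum(lm) > 0) {
      # surrogate: peak indicator detached, gradient through peak heights
      # of FP = sum((1-m) lm yhat) / sum(lm yhat)
      denom <- sum(lm * y_hat)
      if (denom > 0) {
        num <- sum((1 - m) * lm * y_hat)
        grad <- grad + config$beta * lm * ((1 - m) * denom - num) / denom^2
      }
    }
    out$grad <- grad
  }
  out
}
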