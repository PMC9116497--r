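# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the ambient RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a distinct child seed from a base seed; keeps values < 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629
}

# 1-D Gaussian convolution operator (n x n dense matrix) with reflective
# boundary handling folded into the matrix. radius defaults to 4 sigma.
gauss_conv_operator <- function(n, sigma, radius = max(1L, ceiling(4 * sigma))) {
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k <- k / sum(k)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    src <- (i - radius):(i + radius)
    # reflect indices at the borders (half-sample style: 0 -> 1, n+1 -> n)
    src <- ifelse(src < 1, 1 - src, src)
    src <- ifelse(src > n, 2 * n + 1 - src, src)
    for (t in seq_along(src)) A[i, src[t]] <- A[i, src[t]] + k[t]
  }
  A
}

# Separable 2-D Gaussian blur with reflective borders.
gaussian_blur <- function(img, sigma, radius = NULL) {
  sigma <- rep_len(sigma, 2L)
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (is.null(radius)) {
    Ar <- gauss_conv_operator(nrow(img), sigma[1])
    Ac <- gauss_conv_operator(ncol(img), sigma[2])
  } else {
    Ar <- gauss_conv_operator(nrow(img), sigma[1], radius)
    Ac <- gauss_conv_operator(ncol(img), sigma[2], radius)
  }
  Ar %*% img %*% t(Ac)
}

# Strict regional maxima of a matrix within a square neighborhood of the
# given radius; returns a logical matrix. A pixel is a regional maximum if it
# strictly exceeds every other pixel in its neighborhood.
regional_maxima <- function(x, radius = 1L) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(TRUE, nr, nc)
  for (di in -radius:radius) {
    for (dj in -radius:radius) {
      if (di == 0 && dj == 0) next
      shifted <- matrix(-Inf, nr, nc)
      ri <- max(1, 1 + di):min(nr, nr + di)
      rj <- max(1, 1 + dj):min(nc, nc + dj)
      shifted[ri, rj] <- x[ri - di, rj - dj]
      out <- out & (x > shifted)
    }
  }
  out
}
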