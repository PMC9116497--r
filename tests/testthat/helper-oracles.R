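# Independent brute-force oracles, deliberately naive (explicit loops,
# direct formulas) and sharing no code with the package implementation.

oracle_mae <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s / length(a)
}

oracle_ssim <- function(a, b, L = 1) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  va <- sum((a - ma)^2) / n; vb <- sum((b - mb)^2) / n
  cab <- sum((a - ma) * (b - mb)) / n
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  (2 * ma * mb + c1) * (2 * cab + c2) /
    ((ma^2 + mb^2 + c1) * (va + vb + c2))
}

oracle_fp <- function(m, yb) {
  tot <- sum(yb)
  if (tot == 0) return(0)
  outside <- 0
  for (i in seq_along(yb)) if (yb[i] == 1 && m[i] == 0) outside <- outside + 1
  outside / tot
}

oracle_lm <- function(x, radius, min_height) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0L, nr, nc)
  top <- max(x)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (x[i, j] < min_height * top) next
    ok <- TRUE
    for (di in -radius:radius) for (dj in -radius:radius) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
          x[ii, jj] >= x[i, j]) ok <- FALSE
    }
    if (ok) out[i, j] <- 1L
  }
  out
}

# All ordered k-subsets of 1..n (recursive enumeration).
enum_permutations <- function(n, k) {
  if (k == 0) return(matrix(integer(0), 1, 0))
  if (k == 1) return(matrix(seq_len(n), ncol = 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- enum_permutations(n - 1, k - 1)
    rest <- matrix(setdiff(seq_len(n), i)[rest], nrow = nrow(rest))
    out <- rbind(out, cbind(i, rest))
  }
  out
}

# Optimal assignment by enumerating every injection of the smaller point set
# into the larger one; returns the true-positive count at tolerance tol.
oracle_assignment <- function(truth, pred, tol) {
  nt <- nrow(truth); np <- nrow(pred)
  if (min(nt, np) == 0) return(list(tp = 0L, cost = 0))
  D <- sqrt(outer(truth[, 1], pred[, 1], "-")^2 +
            outer(truth[, 2], pred[, 2], "-")^2)
  best <- Inf; best_tp <- 0L
  if (nt <= np) {
    perms <- enum_permutations(np, nt)
    for (r in seq_len(nrow(perms))) {
      d <- D[cbind(seq_len(nt), perms[r, ])]
      if (sum(d) < best) { best <- sum(d); best_tp <- sum(d <= tol) }
    }
  } else {
    perms <- enum_permutations(nt, np)
    for (r in seq_len(nrow(perms))) {
      d <- D[cbind(perms[r, ], seq_len(np))]
      if (sum(d) < best) { best <- sum(d); best_tp <- sum(d <= tol) }
    }
  }
  list(tp = best_tp, cost = best)
}
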