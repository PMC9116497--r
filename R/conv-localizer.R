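#' Set of localized microbubble coordinates
#'
#' @param coordinates n x 2 matrix of (axial, lateral) positions in meters.
#' @param scores Per-detection score (correlation value or blob response).
#' @param frame_index Integer frame label.
#' @param method Character tag, e.g. "conventional" or "dl".
#' @return An object of class \code{localization_set}.
#' @export
localization_set <- function(coordinates, scores = rep(NA_real_,
                                                       nrow(coordinates)),
                             frame_index = 0L, method = "unknown") {
  if (!is.matrix(coordinates)) coordinates <- matrix(coordinates, ncol = 2)
  if (nrow(coordinates) != length(scores)) {
    stop("one score per coordinate required")
  }
  structure(list(coordinates = coordinates, scores = as.numeric(scores),
                 frame_index = as.integer(frame_index), method = method),
            class = "localization_set")
}

#' @export
print.localization_set <- function(x, ...) {
  cat(sprintf("<localization_set> %d detections (%s, frame %d)\n",
              nrow(x$coordinates), x$method, x$frame_index))
  invisible(x)
}

#' PSF sigma of a simulation configuration, in pixels
#'
#' @param config A \code{\link{sim_config}}.
#' @return Length-2 vector c(axial, lateral) of PSF widths in pixel units.
#' @export
psf_sigma_px <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  c(axial = config$sigma_axial / config$grid$pixel_size_axial,
    lateral = config$sigma_lateral / config$grid$pixel_size_lateral)
}

#' Synthesized Gaussian PSF template
#'
#' Unit-peak separable Gaussian used as the matched template for
#' cross-correlation localization.
#'
#' @param sigma_axial,sigma_lateral Gaussian widths in pixels.
#' @param size Template side length(s) in pixels, odd; either a scalar or
#'   c(rows, cols). Default covers 3 sigma on each side.
#' @return Numeric matrix with peak value 1 at the center.
#' @export
gaussian_template <- function(sigma_axial, sigma_lateral,
                              size = 2L * ceiling(3 * c(sigma_axial,
                                                        sigma_lateral)) + 1L) {
  size <- rep_len(as.integer(size), 2L)
  if (any(size %% 2L == 0L) || any(size < 3L)) {
    stop("template size must be odd and >= 3")
  }
  rz <- (size[1] - 1L) / 2L; rx <- (size[2] - 1L) / 2L
  gz <- exp(-((-rz):rz)^2 / (2 * sigma_axial^2))
  gx <- exp(-((-rx):rx)^2 / (2 * sigma_lateral^2))
  gz %o% gx
}

# 1-D correlation operator with zero padding: out[i] = sum_t k[t] f[i+t-r0].
corr1_op_zero <- function(n, k) {
  r0 <- (length(k) + 1L) / 2L
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    src <- i + seq_along(k) - r0
    ok <- src >= 1 & src <= n
    A[i, src[ok]] <- k[ok]
  }
  A
}

#' Normalized cross-correlation map against a separable Gaussian template
#'
#' Zero-normalized cross-correlation (correlation coefficient between the
#' template and each template-sized window of the image), computed with
#' separable filters; windows are zero-padded at the borders.
#'
#' @param img Numeric matrix.
#' @param sigma_axial,sigma_lateral Template widths in pixels.
#' @param size Template size as in \code{\link{gaussian_template}}.
#' @return Matrix of correlation values in [-1, 1] (0 where the local
#'   variance vanishes).
#' @export
ncc_map <- function(img, sigma_axial, sigma_lateral,
                    size = 2L * ceiling(3 * c(sigma_axial,
                                              sigma_lateral)) + 1L) {
  size <- rep_len(as.integer(size), 2L)
  if (any(size > dim(img))) stop("template larger than frame")
  tmpl <- gaussian_template(sigma_axial, sigma_lateral, size)
  K <- length(tmpl)
  gbar <- mean(tmpl)
  denom_t <- sqrt(sum((tmpl - gbar)^2))
  rz <- (size[1] - 1L) / 2L; rx <- (size[2] - 1L) / 2L
  gz <- exp(-((-rz):rz)^2 / (2 * sigma_axial^2))
  gx <- exp(-((-rx):rx)^2 / (2 * sigma_lateral^2))
  Az_g <- corr1_op_zero(nrow(img), gz); Ax_g <- corr1_op_zero(ncol(img), gx)
  Az_1 <- corr1_op_zero(nrow(img), rep(1, size[1]))
  Ax_1 <- corr1_op_zero(ncol(img), rep(1, size[2]))
  G  <- Az_g %*% img %*% t(Ax_g)
  S1 <- Az_1 %*% img %*% t(Ax_1)
  S2 <- Az_1 %*% img^2 %*% t(Ax_1)
  num <- G - gbar * S1
  denf <- sqrt(pmax(S2 - S1^2 / K, 0))
  den <- denf * denom_t
  out <- num * 0
  ok <- den > 1e-12 * max(den)
  out[ok] <- num[ok] / den[ok]
  pmin(pmax(out, -1), 1)
}

# Greedy non-maximum suppression: keep highest-scoring peaks with pairwise
# pixel distance >= min_sep. peaks: matrix with columns row, col, score.
suppress_peaks <- function(peaks, min_sep) {
  if (nrow(peaks) == 0L) return(peaks)
  peaks <- peaks[order(-peaks[, 3]), , drop = FALSE]
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    d2 <- (peaks[which(keep), 1] - peaks[i, 1])^2 +
          (peaks[which(keep), 2] - peaks[i, 2])^2
    keep[i] <- all(d2 >= min_sep^2)
  }
  peaks[keep, , drop = FALSE]
}

#' Conventional cross-correlation microbubble localization
#'
#' Computes the normalized cross-correlation of an envelope frame with a
#' synthesized Gaussian PSF template, keeps regional maxima above a
#' correlation threshold with a minimum mutual separation, and refines each
#' accepted maximum to a subpixel position by the intensity-weighted centroid
#' of the envelope in a small window.
#'
#' @param frame An ENV \code{\link{ulm_frame}}.
#' @param psf_sigma Length-2 vector c(axial, lateral) of template widths in
#'   pixels; see \code{\link{psf_sigma_px}}.
#' @param corr_threshold Minimum correlation to accept a peak (default 0.5).
#' @param min_separation Minimum pixel distance between detections (default
#'   twice the mean template sigma).
#' @param centroid_radius Per-axis half-width of the centroid window in
#'   pixels (default \code{ceiling(psf_sigma)}).
#' @param min_intensity Minimum envelope amplitude at a peak, as a fraction
#'   of the frame maximum (default 0.05). Normalized correlation is
#'   scale-invariant, so without this floor smooth near-zero PSF tails can
#'   correlate perfectly with the template; the relative floor preserves
#'   invariance to global scaling.
#' @param template_size Template size passed to \code{\link{ncc_map}}.
#' @return A \code{\link{localization_set}} with coordinates in meters and
#'   the peak correlation as score.
#' @export
localize_conventional <- function(frame, psf_sigma,
                                  corr_threshold = 0.5,
                                  min_separation = 2 * mean(psf_sigma),
                                  centroid_radius = ceiling(psf_sigma),
                                  min_intensity = 0.05,
                                  template_size = 2L *
                                    ceiling(3 * psf_sigma) + 1L) {
  stopifnot(inherits(frame, "ulm_frame"))
  if (frame$representation != "ENV") {
    stop("conventional localization expects an ENV frame")
  }
  img <- frame$data
  cc <- ncc_map(img, psf_sigma[1], psf_sigma[2], template_size)
  is_max <- regional_maxima(cc, radius = 1L)
  idx <- which(is_max & cc >= corr_threshold &
                 img >= min_intensity * max(img), arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(localization_set(matrix(numeric(0), 0, 2), numeric(0),
                            frame$frame_index %||% 0L, "conventional"))
  }
  peaks <- cbind(idx[, 1], idx[, 2], cc[idx])
  peaks <- suppress_peaks(peaks, min_separation)
  centroid_radius <- rep_len(as.integer(centroid_radius), 2L)
  nr <- nrow(img); nc <- ncol(img)
  coords <- t(apply(peaks, 1L, function(p) {
    ri <- max(1L, p[1] - centroid_radius[1]):min(nr, p[1] + centroid_radius[1])
    ci <- max(1L, p[2] - centroid_radius[2]):min(nc, p[2] + centroid_radius[2])
    w <- img[ri, ci, drop = FALSE]
    sw <- sum(w)
    if (sw <= 0) c(p[1], p[2])
    else c(sum(rowSums(w) * ri) / sw, sum(colSums(w) * ci) / sw)
  }))
  g <- frame$grid
  localization_set(cbind((coords[, 1] - 1) * g$pixel_size_axial,
                         (coords[, 2] - 1) * g$pixel_size_lateral),
                   peaks[, 3], 0L, "conventional")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write localizations to CSV
#'
#' @param locs A \code{\link{localization_set}} or list of them.
#' @param path Output CSV path with columns frame, axial_m, lateral_m, score.
#' @export
write_localizations <- function(locs, path) {
  if (inherits(locs, "localization_set")) locs <- list(locs)
  rows <- do.call(rbind, lapply(locs, function(l) {
    if (nrow(l$coordinates) == 0L) return(NULL)
    data.frame(frame = l$frame_index, axial_m = l$coordinates[, 1],
               lateral_m = l$coordinates[, 2], score = l$scores)
  }))
  if (is.null(rows)) {
    rows <- data.frame(frame = integer(0), axial_m = numeric(0),
                       lateral_m = numeric(0), score = numeric(0))
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
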