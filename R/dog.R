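#' Difference-of-Gaussian blob localization
#'
#' Reads microbubble coordinates off a sharpened (network-enhanced) map by
#' scale-space blob detection: the map is blurred at a geometric ladder of
#' sigmas between \code{min_sigma} and \code{max_sigma}, adjacent blurs are
#' subtracted (scale-normalized), and local maxima of the
#' difference-of-Gaussian stack that are maxima in space and scale and
#' exceed \code{threshold} times the stack maximum become detections. Each
#' detection is refined to a continuous position by the intensity-weighted
#' centroid of the map within the blob radius.
#'
#' @param enhanced Non-negative numeric matrix (the enhanced frame).
#' @param grid An \code{\link{acoustic_grid}} giving the pixel geometry.
#' @param min_sigma,max_sigma Blob scale range in pixels (default 1 and 4;
#'   \code{min_sigma} must be smaller than \code{max_sigma}).
#' @param n_scales Number of sigma steps (default 5).
#' @param threshold Relative response threshold in (0, 1] (default 0.1).
#' @return A \code{\link{localization_set}} with coordinates in meters and
#'   the DoG response as score.
#' @export
dog_localize <- function(enhanced, grid, min_sigma = 1, max_sigma = 4,
                         n_scales = 5L, threshold = 0.1) {
  stopifnot(inherits(grid, "acoustic_grid"))
  if (!all(is.finite(enhanced))) stop("map must be finite")
  if (min_sigma >= max_sigma) stop("min_sigma must be < max_sigma")
  empty <- localization_set(matrix(numeric(0), 0, 2), numeric(0),
                            0L, "dl")
  if (max(enhanced) <= 0) return(empty)
  sigmas <- exp(seq(log(min_sigma), log(max_sigma), length.out = n_scales + 1L))
  blurs <- lapply(sigmas, function(s) gaussian_blur(enhanced, s))
  dogs <- lapply(seq_len(n_scales), function(k) {
    # scale normalization keeps responses comparable across the ladder
    (blurs[[k]] - blurs[[k + 1L]]) * sigmas[k] / (sigmas[k + 1L] - sigmas[k])
  })
  peak_val <- max(vapply(dogs, max, numeric(1)))
  if (peak_val <= 0) return(empty)
  cand <- NULL
  for (k in seq_len(n_scales)) {
    is_max <- regional_maxima(dogs[[k]], radius = 1L) &
      dogs[[k]] >= threshold * peak_val
    if (k > 1L) is_max <- is_max & dogs[[k]] >= dogs[[k - 1L]]
    if (k < n_scales) is_max <- is_max & dogs[[k]] >= dogs[[k + 1L]]
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      cand <- rbind(cand, cbind(idx[, 1], idx[, 2], dogs[[k]][idx],
                                sigmas[k]))
    }
  }
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  # suppress duplicates across scales: keep strongest within a blob radius
  keep <- suppress_peaks(cand[, 1:3, drop = FALSE],
                         min_sep = max(1, sqrt(2) * min_sigma))
  # recover the scale of each kept peak
  sig <- cand[match(paste(keep[, 1], keep[, 2], keep[, 3]),
                    paste(cand[, 1], cand[, 2], cand[, 3])), 4]
  nr <- nrow(enhanced); nc <- ncol(enhanced)
  coords <- t(vapply(seq_len(nrow(keep)), function(i) {
    r <- ceiling(sig[i])
    ri <- max(1L, keep[i, 1] - r):min(nr, keep[i, 1] + r)
    ci <- max(1L, keep[i, 2] - r):min(nc, keep[i, 2] + r)
    w <- enhanced[ri, ci, drop = FALSE]
    sw <- sum(w)
    if (sw <= 0) c(keep[i, 1], keep[i, 2])
    else c(sum(rowSums(w) * ri) / sw, sum(colSums(w) * ci) / sw)
  }, numeric(2)))
  localization_set(cbind((coords[, 1] - 1) * grid$pixel_size_axial,
                         (coords[, 2] - 1) * grid$pixel_size_lateral),
                   keep[, 3], 0L, "dl")
}

#' End-to-end localization of a frame with a trained network
#'
#' Convenience wrapper: enhance then blob-extract.
#'
#' @param model A trained \code{\link{train_unet}} model.
#' @param frame An \code{\link{ulm_frame}} matching the model's
#'   representation.
#' @param ... Passed to \code{\link{dog_localize}}.
#' @return A \code{\link{localization_set}}.
#' @export
localize_dl <- function(model, frame, ...) {
  dog_localize(enhance_frame(model, frame), frame$grid, ...)
}
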