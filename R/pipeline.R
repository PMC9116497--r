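#' SVD clutter filtering of a frame stack
#'
#' Reshapes a rows x cols x time stack into its Casorati matrix (pixels x
#' time), takes the singular value decomposition, retains singular
#' components \code{low_cutoff..high_cutoff} (1-based) and reshapes back.
#' Slowly varying tissue signal concentrates in the largest components, so
#' the default removes only the first; microbubble signal survives in the
#' middle band.
#'
#' @param stack 3-D numeric or complex array (rows x cols x time, time >= 2).
#' @param low_cutoff First retained singular component (default 2: remove
#'   the largest).
#' @param high_cutoff Last retained component (default: full rank).
#' @return Filtered stack of the same shape.
#' @export
svd_clutter_filter <- function(stack, low_cutoff = 2L, high_cutoff = NULL) {
  d <- dim(stack)
  if (length(d) != 3L || d[3] < 2L) stop("stack must be rows x cols x time")
  rank <- min(d[1] * d[2], d[3])
  if (is.null(high_cutoff)) high_cutoff <- rank
  if (low_cutoff < 1L || high_cutoff > rank || low_cutoff > high_cutoff) {
    stop("cutoffs must satisfy 1 <= low <= high <= rank")
  }
  cas <- matrix(stack, d[1] * d[2], d[3])
  sv <- svd(cas)
  keep <- low_cutoff:high_cutoff
  rec <- sv$u[, keep, drop = FALSE] %*%
    (sv$d[keep] * t(Conj(sv$v[, keep, drop = FALSE])))
  array(rec, d)
}

#' Density map of accumulated localizations
#'
#' Each localization increments the count of its nearest pixel (ties toward
#' the smaller index); raw accumulation with no pairing or tracking. The
#' total count equals the number of accepted localizations.
#'
#' @param localizations List of \code{\link{localization_set}}s (or a single
#'   one).
#' @param grid An \code{\link{acoustic_grid}}.
#' @return An object of class \code{density_map}: \code{counts} (integer
#'   matrix), \code{n_frames}, \code{grid}.
#' @export
accumulate_density <- function(localizations, grid) {
  stopifnot(inherits(grid, "acoustic_grid"))
  if (inherits(localizations, "localization_set")) {
    localizations <- list(localizations)
  }
  counts <- matrix(0L, grid$n_rows, grid$n_cols)
  for (loc in localizations) {
    if (nrow(loc$coordinates) == 0L) next
    r <- ceiling(loc$coordinates[, 1] / grid$pixel_size_axial - 0.5) + 1L
    c <- ceiling(loc$coordinates[, 2] / grid$pixel_size_lateral - 0.5) + 1L
    if (any(r < 1 | r > grid$n_rows | c < 1 | c > grid$n_cols)) {
      stop("localization outside the field of view")
    }
    for (k in seq_along(r)) counts[r[k], c[k]] <- counts[r[k], c[k]] + 1L
  }
  structure(list(counts = counts,
                 n_frames = length(localizations), grid = grid),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d px, %d frames, %d localizations\n",
              nrow(x$counts), ncol(x$counts), x$n_frames, sum(x$counts)))
  invisible(x)
}

#' Sliding-window accumulation of enhanced frames
#'
#' Streaming high-resolution display: output frame t is the sum of the
#' latest W enhanced frames (fewer during warm-up). Internally the newest
#' frame is added and the frame leaving the window subtracted, which is
#' algebraically identical to direct summation.
#'
#' @param frames List of numeric matrices (enhanced frames), all the same
#'   size.
#' @param window_length Window size W >= 1.
#' @param normalize If TRUE, each output frame is scaled to unit maximum for
#'   rendering (raw sums are what the quantitative path uses).
#' @return List of output frames, one per input frame.
#' @export
sliding_window_display <- function(frames, window_length,
                                   normalize = FALSE) {
  if (window_length < 1L) stop("window_length must be >= 1")
  if (length(frames) == 0L) return(list())
  acc <- frames[[1L]] * 0
  out <- vector("list", length(frames))
  for (t in seq_along(frames)) {
    acc <- acc + frames[[t]]
    if (t > window_length) acc <- acc - frames[[t - window_length]]
    out[[t]] <- if (normalize && max(acc) > 0) acc / max(acc) else acc
  }
  out
}

#' Average profile of a density map across the tube direction
#'
#' For the two-tube phantom: averages the accumulated counts along the
#' direction the tubes run, yielding a 1-D profile across them.
#'
#' @param density A \code{\link{accumulate_density}} result or count matrix.
#' @param orientation \code{"horizontal"} (tubes run laterally; average over
#'   columns) or \code{"vertical"}.
#' @return Numeric vector (one value per pixel across the tubes).
#' @export
density_profile <- function(density, orientation = c("horizontal",
                                                     "vertical")) {
  orientation <- match.arg(orientation)
  counts <- if (inherits(density, "density_map")) density$counts else density
  if (orientation == "horizontal") rowMeans(counts) else colMeans(counts)
}

#' Count resolved peaks in a 1-D profile
#'
#' Smooths the profile with a small Gaussian and counts strict local maxima
#' whose height is at least \code{min_height} of the profile maximum and
#' whose prominence (drop to the highest saddle separating it from a larger
#' peak) is at least \code{min_prominence} of the maximum. Two tubes are
#' resolved when the profile has two such peaks. The defaults smooth at
#' 1.5 samples (about the single-bubble localization uncertainty, so
#' counting is insensitive to bin noise) and demand a dip of a quarter of
#' the peak height, close to the ~26 percent intensity dip of two point
#' sources at the Rayleigh limit.
#'
#' @param profile Numeric vector.
#' @param smooth_sigma Gaussian smoothing sigma in samples (default 1.5).
#' @param min_height Height threshold, fraction of max (default 0.3).
#' @param min_prominence Prominence threshold, fraction of max (default
#'   0.25).
#' @return Number of peaks (integer).
#' @export
count_profile_peaks <- function(profile, smooth_sigma = 1.5,
                                min_height = 0.3, min_prominence = 0.25) {
  n <- length(profile)
  if (n < 3L) return(0L)
  p <- if (smooth_sigma > 0) {
    as.numeric(gauss_conv_operator(n, smooth_sigma) %*% profile)
  } else profile
  top <- max(p)
  if (top <= 0) return(0L)
  is_peak <- vapply(2:(n - 1L), function(i) {
    p[i] > p[i - 1L] && p[i] >= p[i + 1L] && p[i] >= min_height * top
  }, logical(1))
  peaks <- which(is_peak) + 1L
  if (length(peaks) <= 1L) return(length(peaks))
  # prominence: lowest point between this peak and the nearest higher peak
  keep <- vapply(peaks, function(i) {
    higher <- peaks[p[peaks] > p[i]]
    if (length(higher) == 0L) return(TRUE)   # global max always kept
    j <- higher[which.min(abs(higher - i))]
    saddle <- min(p[min(i, j):max(i, j)])
    (p[i] - saddle) >= min_prominence * top
  }, logical(1))
  sum(keep)
}

#' Run the full localization pipeline on a frame sequence
#'
#' Orchestrates localization over simulated (or user-supplied) frames:
#' optional SVD clutter filtering, per-frame localization with either the
#' conventional cross-correlation localizer or a trained network, density
#' accumulation, and (when ground truth is present) pairing-based
#' evaluation. Simulated sequences skip clutter filtering by default, since
#' the simulator contains no tissue signal.
#'
#' @param frames List of per-frame lists (\code{frame_rf},
#'   \code{frame_env}, optional \code{field}) as produced by
#'   \code{\link{simulate_sequence}}.
#' @param method \code{"conventional"} or \code{"dl"}.
#' @param config A \code{\link{sim_config}} (supplies the PSF for the
#'   conventional template and the grid).
#' @param model Trained \code{\link{train_unet}} model (required for
#'   \code{method = "dl"}).
#' @param tol Pairing tolerance in meters (default 5 pixels).
#' @param clutter_filter If TRUE, apply \code{\link{svd_clutter_filter}} to
#'   the envelope stack before localization.
#' @param window_length If not NULL, also return the sliding-window display
#'   stream of the enhanced (DL) or envelope (conventional) frames.
#' @param ... Extra arguments for the localizer.
#' @return List with \code{localizations} (per frame), \code{density}
#'   (\code{density_map}), \code{metrics} (per-frame detection metrics
#'   data.frame, when ground truth present), and optionally \code{display}.
#' @export
run_ulm <- function(frames, method = c("conventional", "dl"), config,
                    model = NULL, tol = 5 * config$grid$pixel_size_axial,
                    clutter_filter = FALSE, window_length = NULL, ...) {
  method <- match.arg(method)
  stopifnot(inherits(config, "sim_config"))
  if (method == "dl" && is.null(model)) stop("dl method requires a model")
  if (method == "dl" &&
      model$spec$representation == "RF" &&
      is.null(frames[[1L]]$frame_rf)) {
    stop("model expects RF input but frames carry none")
  }
  if (clutter_filter && length(frames) >= 2L) {
    stack <- simplify2array(lapply(frames, function(f) f$frame_env$data))
    filt <- svd_clutter_filter(stack)
    for (t in seq_along(frames)) {
      frames[[t]]$frame_env$data <- pmax(filt[, , t], 0)
    }
  }
  sig <- psf_sigma_px(config)
  enhanced <- if (method == "dl") vector("list", length(frames)) else NULL
  locs <- vector("list", length(frames))
  for (t in seq_along(frames)) {
    if (method == "conventional") {
      locs[[t]] <- localize_conventional(frames[[t]]$frame_env, sig, ...)
    } else {
      fr <- if (model$spec$representation == "RF") frames[[t]]$frame_rf
            else frames[[t]]$frame_env
      enh <- enhance_frame(model, fr)
      enhanced[[t]] <- enh
      locs[[t]] <- dog_localize(enh, fr$grid, ...)
    }
    locs[[t]]$frame_index <- t - 1L
  }
  out <- list(localizations = locs,
              density = accumulate_density(locs, config$grid))
  if (!is.null(frames[[1L]]$field)) {
    out$metrics <- do.call(rbind, lapply(seq_along(frames), function(t) {
      met <- detection_metrics(
        pair_detections(frames[[t]]$field, locs[[t]], tol))
      data.frame(frame = t - 1L, fdr = met$fdr, miss_rate = met$miss_rate,
                 mean_error = met$mean_error)
    }))
  }
  if (!is.null(window_length)) {
    src <- if (method == "dl") enhanced
           else lapply(frames, function(f) f$frame_env$data)
    out$display <- sliding_window_display(src, window_length)
  }
  out
}
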