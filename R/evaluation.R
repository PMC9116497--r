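#' Pair predicted and true microbubble positions
#'
#' Globally optimal one-to-one assignment between ground-truth and predicted
#' positions minimizing total Euclidean distance (Hungarian algorithm on the
#' pairwise distance matrix). Assigned pairs farther apart than \code{tol}
#' are broken, contributing one false negative and one false positive;
#' unmatched truths are false negatives and unmatched predictions false
#' positives. A greedy nearest-neighbor alternative is available for
#' sensitivity analysis.
#'
#' @param truth An \code{\link{mb_field}} (or n x 2 coordinate matrix).
#' @param pred A \code{\link{localization_set}} (or m x 2 coordinate matrix).
#' @param tol Pairing tolerance in meters (> 0).
#' @param method \code{"optimal"} (default) or \code{"greedy"}.
#' @return An object of class \code{pairing_result}: data.frame
#'   \code{pairs} (truth_index, pred_index, distance; true positives only),
#'   counts \code{tp}, \code{fp}, \code{fn}, and \code{tol}.
#' @export
pair_detections <- function(truth, pred, tol,
                            method = c("optimal", "greedy")) {
  method <- match.arg(method)
  if (tol <= 0) stop("tol must be positive")
  tp_coords <- if (inherits(truth, "mb_field")) truth$positions else truth
  pp_coords <- if (inherits(pred, "localization_set")) pred$coordinates else pred
  if (!is.matrix(tp_coords)) tp_coords <- matrix(tp_coords, ncol = 2)
  if (!is.matrix(pp_coords)) pp_coords <- matrix(pp_coords, ncol = 2)
  nt <- nrow(tp_coords); np <- nrow(pp_coords)
  pairs <- data.frame(truth_index = integer(0), pred_index = integer(0),
                      distance = numeric(0))
  if (nt > 0L && np > 0L) {
    D <- sqrt(outer(tp_coords[, 1], pp_coords[, 1], "-")^2 +
              outer(tp_coords[, 2], pp_coords[, 2], "-")^2)
    assign <- if (method == "optimal") {
      if (nt <= np) {
        sol <- clue::solve_LSAP(D)
        cbind(seq_len(nt), as.integer(sol))
      } else {
        sol <- clue::solve_LSAP(t(D))
        cbind(as.integer(sol), seq_len(np))
      }
    } else {
      # greedy: repeatedly match the closest remaining pair
      out <- NULL
      Dm <- D
      for (k in seq_len(min(nt, np))) {
        ij <- arrayInd(which.min(Dm), dim(Dm))
        out <- rbind(out, ij)
        Dm[ij[1], ] <- Inf; Dm[, ij[2]] <- Inf
      }
      out
    }
    d <- D[assign]
    ok <- d <= tol
    pairs <- data.frame(truth_index = assign[ok, 1],
                        pred_index = assign[ok, 2], distance = d[ok])
  }
  tp <- nrow(pairs)
  structure(list(pairs = pairs, tp = tp, fp = np - tp, fn = nt - tp,
                 tol = tol, n_truth = nt, n_pred = np),
            class = "pairing_result")
}

#' @export
print.pairing_result <- function(x, ...) {
  cat(sprintf("<pairing_result> TP %d, FP %d, FN %d (tol %.3g m)\n",
              x$tp, x$fp, x$fn, x$tol))
  invisible(x)
}

#' Detection metrics from a pairing
#'
#' False discovery rate FP/(FP+TP), miss rate FN/(FN+TP) and mean Euclidean
#' localization error over the true-positive pairs. Empty denominators give
#' 0 with the \code{degenerate} flag set.
#'
#' @param pairing A \code{\link{pair_detections}} result.
#' @return List with \code{fdr}, \code{miss_rate}, \code{mean_error} (m) and
#'   \code{degenerate}.
#' @export
detection_metrics <- function(pairing) {
  stopifnot(inherits(pairing, "pairing_result"))
  degenerate <- FALSE
  fdr <- if (pairing$fp + pairing$tp > 0) {
    pairing$fp / (pairing$fp + pairing$tp)
  } else { degenerate <- TRUE; 0 }
  miss <- if (pairing$fn + pairing$tp > 0) {
    pairing$fn / (pairing$fn + pairing$tp)
  } else { degenerate <- TRUE; 0 }
  err <- if (pairing$tp > 0) mean(pairing$pairs$distance) else {
    degenerate <- TRUE; 0
  }
  list(fdr = fdr, miss_rate = miss, mean_error = err,
       degenerate = degenerate)
}

#' Localization performance versus microbubble concentration
#'
#' For each concentration, simulates \code{n_reps} independent frames,
#' localizes each with the supplied localizer and reports the mean and
#' standard deviation of FDR, miss rate and mean localization error across
#' repetitions.
#'
#' @param localizer Function taking a per-frame sample (list with
#'   \code{frame_rf}, \code{frame_env}, \code{field}) and returning a
#'   \code{\link{localization_set}}.
#' @param concentrations Increasing vector of concentrations (MBs/mm^2).
#' @param config A \code{\link{sim_config}}.
#' @param n_reps Repetitions per concentration.
#' @param tol Pairing tolerance in meters (default 5 pixels).
#' @param mask Optional \code{\link{vessel_mask}} constraining placement.
#' @param seed Integer seed.
#' @return data.frame with one row per concentration: means and SDs of the
#'   three metrics.
#' @export
concentration_sweep <- function(localizer, concentrations, config,
                                n_reps = 10L,
                                tol = 5 * config$grid$pixel_size_axial,
                                mask = NULL, seed = 1L) {
  stopifnot(n_reps >= 1)
  rows <- lapply(seq_along(concentrations), function(ci) {
    conc <- concentrations[ci]
    m <- vapply(seq_len(n_reps), function(r) {
      s <- child_seed(seed, ci * 1000L + r)
      frames <- simulate_sequence(mask, 1L, conc, config, seed = s)
      loc <- localizer(frames[[1L]])
      met <- detection_metrics(pair_detections(frames[[1L]]$field, loc, tol))
      c(met$fdr, met$miss_rate, met$mean_error)
    }, numeric(3))
    data.frame(concentration = conc,
               fdr = mean(m[1, ]), fdr_sd = stats::sd(m[1, ]),
               miss_rate = mean(m[2, ]), miss_rate_sd = stats::sd(m[2, ]),
               mean_error = mean(m[3, ]), mean_error_sd = stats::sd(m[3, ]))
  })
  out <- do.call(rbind, rows)
  out$fdr_sd[is.na(out$fdr_sd)] <- 0
  out$miss_rate_sd[is.na(out$miss_rate_sd)] <- 0
  out$mean_error_sd[is.na(out$mean_error_sd)] <- 0
  out
}

#' Concentration at which a localizer exceeds 50 percent miss rate
#'
#' First concentration (in increasing order) whose mean miss rate exceeds
#' the threshold; \code{Inf} if never exceeded.
#'
#' @param curve data.frame with columns \code{concentration} and
#'   \code{miss_rate} (as from \code{\link{concentration_sweep}}).
#' @param threshold Miss-rate threshold (default 0.5).
#' @return Concentration (MBs/mm^2) or \code{Inf}.
#' @export
breakpoint_concentration <- function(curve, threshold = 0.5) {
  if (nrow(curve) == 0L) stop("empty curve")
  if (is.unsorted(curve$concentration)) stop("concentrations must increase")
  hit <- which(curve$miss_rate > threshold)
  if (length(hit) == 0L) Inf else curve$concentration[hit[1L]]
}

#' Vessel-pixel confusion metrics of an accumulated localization map
#'
#' Classifies every pixel by (inside vs outside vessel) x (localized vs
#' not): true positives are vessel pixels covered by at least one
#' localization, false negatives vessel pixels never localized, false
#' positives localized pixels outside vessels, true negatives the rest.
#' Vessel FDR and vessel miss rate follow the same forms as the detection
#' metrics.
#'
#' @param mask A \code{\link{vessel_mask}}.
#' @param density Non-negative count matrix on the same grid (see
#'   \code{\link{accumulate_density}}).
#' @return List with counts \code{tp}, \code{fp}, \code{fn}, \code{tn},
#'   rates \code{vessel_fdr}, \code{vessel_miss_rate}, and
#'   \code{confusion} - a character matrix with values "TP", "FP", "FN",
#'   "TN".
#' @export
vessel_pixel_metrics <- function(mask, density) {
  stopifnot(inherits(mask, "vessel_mask"))
  dm <- if (inherits(density, "density_map")) density$counts else density
  if (!identical(dim(dm), dim(mask$mask))) stop("grid mismatch")
  inside <- mask$mask == 1L
  hit <- dm > 0
  tp <- sum(inside & hit); fn <- sum(inside & !hit)
  fp <- sum(!inside & hit); tn <- sum(!inside & !hit)
  conf <- matrix("TN", nrow(dm), ncol(dm))
  conf[inside & hit] <- "TP"; conf[inside & !hit] <- "FN"
  conf[!inside & hit] <- "FP"
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       vessel_fdr = if (fp + tp > 0) fp / (fp + tp) else 0,
       vessel_miss_rate = if (fn + tp > 0) fn / (fn + tp) else 0,
       confusion = conf)
}

#' Write a vessel confusion map as a color image
#'
#' Red = vessel pixels covered by localizations (TP), blue = localizations
#' outside vessels (FP), white = missed vessel pixels (FN), black =
#' background (TN).
#'
#' @param metrics Result of \code{\link{vessel_pixel_metrics}}.
#' @param path PNG output path.
#' @export
write_confusion_map <- function(metrics, path) {
  if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' required")
  conf <- metrics$confusion
  img <- array(0, c(nrow(conf), ncol(conf), 3))
  img[, , 1][conf == "TP"] <- 1
  img[, , 3][conf == "FP"] <- 1
  for (k in 1:3) img[, , k][conf == "FN"] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' Serializes metric lists or sweep data frames (scalars unboxed, full
#' precision).
#'
#' @param report A list or data.frame of metrics.
#' @param path Output JSON path.
#' @export
write_eval_report <- function(report, path) {
  report$confusion <- NULL  # image-sized fields belong in image files
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Vessel saturation time
#'
#' Accumulates the union of localized vessel pixels over frames and returns
#' the acquisition time at which coverage first reaches \code{fraction} of
#' the vessel pixels: \code{(index of that frame, 1-based) / frame_rate}.
#' Localizations are rounded to the nearest pixel (ties toward the smaller
#' index); only pixels inside the mask count toward coverage.
#'
#' @param mask A \code{\link{vessel_mask}} (must contain vessel pixels).
#' @param localizations List of per-frame \code{\link{localization_set}}s.
#' @param frame_rate Acquisition frame rate in Hz.
#' @param fraction Coverage target (default 0.9, i.e. t90).
#' @return List with \code{time} (seconds; \code{Inf} when coverage is never
#'   reached), \code{frames_needed}, and \code{coverage} (per-frame coverage
#'   fraction vector).
#' @export
saturation_time <- function(mask, localizations, frame_rate,
                            fraction = 0.9) {
  stopifnot(inherits(mask, "vessel_mask"))
  if (frame_rate <= 0) stop("frame_rate must be positive")
  n_vessel <- sum(mask$mask)
  if (n_vessel == 0L) stop("mask has no vessel pixels")
  g <- mask$grid
  covered <- matrix(FALSE, nrow(mask$mask), ncol(mask$mask))
  coverage <- numeric(length(localizations))
  hit_frame <- NA_integer_
  for (t in seq_along(localizations)) {
    loc <- localizations[[t]]
    if (nrow(loc$coordinates) > 0L) {
      r <- ceiling(loc$coordinates[, 1] / g$pixel_size_axial - 0.5) + 1L
      c <- ceiling(loc$coordinates[, 2] / g$pixel_size_lateral - 0.5) + 1L
      ok <- r >= 1 & r <= nrow(covered) & c >= 1 & c <= ncol(covered)
      idx <- cbind(r[ok], c[ok])
      covered[idx] <- TRUE
    }
    coverage[t] <- sum(covered & mask$mask == 1L) / n_vessel
    if (is.na(hit_frame) && coverage[t] >= fraction) hit_frame <- t
  }
  list(time = if (is.na(hit_frame)) Inf else hit_frame / frame_rate,
       frames_needed = hit_frame, coverage = coverage)
}
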