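#' Binary vessel mask
#'
#' A binary map of vessel lumen (1) versus background (0) on a physical pixel
#' grid. Masks constrain microbubble placement in the simulator and define
#' the ground truth for vessel-domain evaluation and the false-positive loss
#' term during network training.
#'
#' @param mask Matrix of 0/1 (or logical) values; dimensions must match the
#'   grid.
#' @param grid An \code{\link{acoustic_grid}}.
#' @param provenance \code{"procedural"} or \code{"binarized"}.
#' @param seed Optional integer recording the generating seed.
#' @return An object of class \code{vessel_mask} with fields \code{mask}
#'   (integer matrix), \code{grid}, \code{provenance}, \code{seed}.
#' @export
vessel_mask <- function(mask, grid, provenance = c("procedural", "binarized"),
                        seed = NULL) {
  stopifnot(inherits(grid, "acoustic_grid"))
  provenance <- match.arg(provenance)
  if (is.logical(mask)) mask <- mask + 0L
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    stop("mask must be a binary matrix")
  }
  if (nrow(mask) != grid$n_rows || ncol(mask) != grid$n_cols) {
    stop("mask dimensions must match the grid")
  }
  storage.mode(mask) <- "integer"
  structure(list(mask = mask, grid = grid, provenance = provenance,
                 seed = seed),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d x %d px (%s), vessel fraction %.3f\n",
              nrow(x$mask), ncol(x$mask), x$provenance, mean(x$mask)))
  invisible(x)
}

#' Vessel-pixel fraction of a mask
#' @param mask A \code{\link{vessel_mask}}.
#' @return Fraction of pixels inside vessels.
#' @export
vessel_fraction <- function(mask) mean(mask$mask)

#' Binarize a grayscale vessel image by adaptive thresholding
#'
#' Segments bright (or dark) vessels from an optical image using a local
#' threshold computed from the Gaussian-weighted mean of neighboring pixels.
#' A pixel is foreground when its value strictly exceeds
#' \code{2 * (1 - sensitivity)} times the local mean (bright polarity; the
#' comparison is reversed for dark vessels after inverting the image), so
#' sensitivity 0.5 compares against the local mean itself and larger
#' sensitivities admit more pixels. A constant image yields an all-background
#' mask.
#'
#' @param image Numeric matrix (grayscale) or H x W x 3 array (RGB, from
#'   which one channel is taken).
#' @param grid An \code{\link{acoustic_grid}} describing the pixel geometry;
#'   defaults to an isotropic 4.9 um grid of the image's size.
#' @param window_size Odd window width in pixels over which the local mean is
#'   taken; default one eighth of the smaller image dimension, rounded to odd.
#' @param sensitivity Fraction in [0, 1]; default 0.5.
#' @param polarity \code{"bright"} for vessels brighter than background,
#'   \code{"dark"} otherwise.
#' @param channel For RGB input, which channel to use; the green channel
#'   (default) usually has the best vessel contrast.
#' @return A \code{\link{vessel_mask}} with provenance \code{"binarized"}.
#' @export
binarize_vessel_image <- function(image, grid = NULL,
                                  window_size = NULL, sensitivity = 0.5,
                                  polarity = c("bright", "dark"),
                                  channel = 2L) {
  polarity <- match.arg(polarity)
  if (length(dim(image)) == 3L) image <- image[, , channel]
  if (!is.matrix(image) || length(image) == 0L) stop("empty image")
  if (sensitivity < 0 || sensitivity > 1) stop("sensitivity must be in [0, 1]")
  if (is.null(window_size)) {
    window_size <- floor(min(dim(image)) / 8)
    if (window_size %% 2 == 0) window_size <- window_size + 1L
  }
  if (window_size < 3 || window_size %% 2 == 0) {
    stop("window_size must be odd and >= 3")
  }
  if (polarity == "dark") image <- max(image) - image
  rng <- range(image)
  img <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1]) else image * 0
  radius <- (window_size - 1L) / 2L
  local_mean <- gaussian_blur(img, sigma = window_size / 6, radius = radius)
  mask <- (img > 2 * (1 - sensitivity) * local_mean) + 0L
  if (is.null(grid)) {
    grid <- acoustic_grid(n_rows = nrow(image), n_cols = ncol(image))
  }
  vessel_mask(mask, grid, provenance = "binarized")
}

#' Procedurally generate a vascular mask
#'
#' Draws connected tubular structures by correlated random walks with
#' branching: each trunk starts at a random border point, meanders across the
#' field, stamps disks of slowly varying diameter, and spawns narrower
#' branches with a fixed per-step probability. This produces masks with the
#' multi-scale vessel diameters (large trunks feeding small branches) that
#' matter when vessel structure is used to constrain microbubble placement,
#' in lieu of optical vessel imagery.
#'
#' @param seed Integer seed; the mask is deterministic given (seed, params).
#' @param grid An \code{\link{acoustic_grid}}.
#' @param n_trunks Number of primary vessels (default 3).
#' @param branch_prob Per-step probability that a walker spawns a branch
#'   (default 0.02).
#' @param diameter_range_px Range of vessel diameters in pixels (default
#'   c(3, 10)).
#' @param meander Standard deviation (radians) of the per-step heading
#'   change (default 0.15).
#' @param allow_empty If TRUE, \code{n_trunks = 0} returns an empty mask
#'   instead of an error.
#' @return A \code{\link{vessel_mask}} with provenance \code{"procedural"}.
#' @export
generate_vessel_map <- function(seed, grid, n_trunks = 3L, branch_prob = 0.02,
                                diameter_range_px = c(3, 10), meander = 0.15,
                                allow_empty = FALSE) {
  stopifnot(inherits(grid, "acoustic_grid"))
  nr <- grid$n_rows; nc <- grid$n_cols
  if (max(diameter_range_px) >= min(nr, nc)) {
    stop("diameter_range_px must fit inside the grid")
  }
  mask <- matrix(0L, nr, nc)
  if (n_trunks < 1L) {
    if (allow_empty) return(vessel_mask(mask, grid, "procedural", seed))
    stop("n_trunks must be >= 1 (or set allow_empty = TRUE)")
  }
  mask <- with_seed(seed, {
    # walker queue: list of (row, col, heading, diameter, depth)
    queue <- lapply(seq_len(n_trunks), function(i) {
      side <- sample(4L, 1L)
      pos <- switch(side,
        c(1, runif(1, 1, nc)),                # top edge, heading down
        c(nr, runif(1, 1, nc)),               # bottom edge, heading up
        c(runif(1, 1, nr), 1),                # left edge, heading right
        c(runif(1, 1, nr), nc))               # right edge, heading left
      heading <- switch(side, pi / 2, -pi / 2, 0, pi) + runif(1, -0.4, 0.4)
      d <- runif(1, mean(diameter_range_px), max(diameter_range_px))
      list(r = pos[1], c = pos[2], h = heading, d = d, depth = 0L)
    })
    max_steps <- 4L * (nr + nc)
    max_walkers <- 12L * n_trunks
    spawned <- length(queue)
    while (length(queue) > 0L) {
      w <- queue[[1L]]; queue <- queue[-1L]
      for (step in seq_len(max_steps)) {
        rad <- max(0.5, w$d / 2)
        ri <- max(1L, floor(w$r - rad)):min(nr, ceiling(w$r + rad))
        ci <- max(1L, floor(w$c - rad)):min(nc, ceiling(w$c + rad))
        dr <- outer(ri - w$r, rep(1, length(ci)))
        dc <- outer(rep(1, length(ri)), ci - w$c)
        mask[ri, ci][dr^2 + dc^2 <= rad^2] <- 1L
        w$h <- w$h + stats::rnorm(1, 0, meander)
        # diameter drifts slowly within range
        w$d <- min(max(w$d * exp(stats::rnorm(1, 0, 0.03)),
                       min(diameter_range_px)), max(diameter_range_px))
        w$r <- w$r + sin(w$h); w$c <- w$c + cos(w$h)
        if (w$r < 1 || w$r > nr || w$c < 1 || w$c > nc) break
        if (spawned < max_walkers && w$depth < 3L &&
            stats::runif(1) < branch_prob) {
          spawned <- spawned + 1L
          queue[[length(queue) + 1L]] <- list(
            r = w$r, c = w$c,
            h = w$h + sample(c(-1, 1), 1L) * stats::runif(1, 0.4, 1.1),
            d = max(min(diameter_range_px), w$d * stats::runif(1, 0.4, 0.7)),
            depth = w$depth + 1L)
        }
      }
    }
    mask
  })
  if (sum(mask) == 0L) stop("procedural parameters produced no vessel pixels")
  vessel_mask(mask, grid, "procedural", seed)
}

#' Two-parallel-tube resolution phantom
#'
#' Builds the synthetic two-vessel phantom used to probe resolving power:
#' two straight tubes of fixed diameter separated by a configurable gap.
#' \code{orientation = "horizontal"} runs the tubes laterally (axial
#' separation); \code{"vertical"} runs them axially (lateral separation).
#' With 4.9 um pixels, a 5-pixel diameter and gaps of 2/6/10 pixels probe
#' separations of 0.13, 0.38 and 0.64 wavelengths at 20 MHz.
#'
#' @param grid An \code{\link{acoustic_grid}}.
#' @param diameter_px Tube diameter in pixels (default 5).
#' @param separation_px Edge-to-edge gap between the tubes in pixels.
#' @param orientation Direction the tubes run.
#' @return A \code{\link{vessel_mask}} with two connected components when
#'   \code{separation_px > 0}.
#' @export
two_tube_phantom <- function(grid, diameter_px = 5L, separation_px = 10L,
                             orientation = c("horizontal", "vertical")) {
  stopifnot(inherits(grid, "acoustic_grid"))
  orientation <- match.arg(orientation)
  nr <- grid$n_rows; nc <- grid$n_cols
  span <- 2L * diameter_px + separation_px
  n_across <- if (orientation == "horizontal") nr else nc
  if (span > n_across) stop("tubes do not fit inside the grid")
  first <- floor((n_across - span) / 2) + 1L
  rows_a <- first:(first + diameter_px - 1L)
  rows_b <- (first + diameter_px + separation_px):(first + span - 1L)
  mask <- matrix(0L, nr, nc)
  if (orientation == "horizontal") {
    mask[rows_a, ] <- 1L; mask[rows_b, ] <- 1L
  } else {
    mask[, rows_a] <- 1L; mask[, rows_b] <- 1L
  }
  vessel_mask(mask, grid, "procedural")
}

#' Randomly crop a square subregion from a vessel mask
#'
#' Emulates sampling training fields from a large vessel map: a random
#' top-left corner is drawn uniformly and a \code{roi_size} x \code{roi_size}
#' crop is returned with grid metadata updated.
#'
#' @param mask A \code{\link{vessel_mask}}.
#' @param roi_size Crop side length in pixels; must not exceed either mask
#'   dimension.
#' @param seed Integer seed (deterministic crop) or NULL.
#' @return A \code{\link{vessel_mask}} of size roi_size x roi_size.
#' @export
sample_roi <- function(mask, roi_size, seed = NULL) {
  stopifnot(inherits(mask, "vessel_mask"))
  nr <- nrow(mask$mask); nc <- ncol(mask$mask)
  if (roi_size > nr || roi_size > nc) stop("roi larger than mask")
  corner <- with_seed(seed, c(sample.int(nr - roi_size + 1L, 1L),
                              sample.int(nc - roi_size + 1L, 1L)))
  sub <- mask$mask[corner[1]:(corner[1] + roi_size - 1L),
                   corner[2]:(corner[2] + roi_size - 1L), drop = FALSE]
  g <- mask$grid
  grid <- acoustic_grid(n_rows = roi_size, n_cols = roi_size,
                        pixel_size_axial = g$pixel_size_axial,
                        pixel_size_lateral = g$pixel_size_lateral,
                        speed_of_sound = g$speed_of_sound,
                        center_frequency = g$center_frequency,
                        sampling_frequency = g$sampling_frequency)
  vessel_mask(sub, grid, mask$provenance, seed)
}

#' Read or write a mask as an 8-bit image
#'
#' @param mask A \code{\link{vessel_mask}}.
#' @param path Output path; format chosen by extension (.tif/.tiff or .png).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "vessel_mask"))
  img <- mask$mask + 0  # numeric in [0,1]
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required")
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' required")
    png::writePNG(img, path)
  } else stop("unsupported extension (use .tif or .png)")
  invisible(path)
}

#' @rdname write_mask
#' @param path Path of a TIFF or PNG image.
#' @param ... Passed to \code{\link{binarize_vessel_image}} when the image is
#'   not already binary.
#' @export
read_mask <- function(path, ...) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required")
    tiff::readTIFF(path)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' required")
    png::readPNG(path)
  } else stop("unsupported extension (use .tif or .png)")
  if (length(dim(img)) == 3L) img <- img[, , 2L]
  if (all(img %in% c(0, 1))) {
    vessel_mask(img + 0L, acoustic_grid(nrow(img), ncol(img)), "binarized")
  } else {
    binarize_vessel_image(img, ...)
  }
}
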