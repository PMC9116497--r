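#' Acoustic imaging grid
#'
#' Describes the physical pixel grid on which frames live: speed of sound,
#' center and sampling frequency of the imaging system, pixel sizes, and the
#' grid dimensions. Pixels are center-registered: pixel \code{(1, 1)} sits at
#' physical position (0, 0), row 1 is the shallowest axial depth, and
#' positions are expressed in meters as (axial, lateral) pairs throughout the
#' package.
#'
#' @param n_rows,n_cols Grid dimensions (axial x lateral), positive integers.
#' @param pixel_size Isotropic pixel size in meters; shorthand that sets both
#'   axial and lateral sizes. Default 4.9e-6 m.
#' @param pixel_size_axial,pixel_size_lateral Per-axis pixel sizes in meters;
#'   override \code{pixel_size} (the axial grid of RF data is typically 4x
#'   denser than the lateral one).
#' @param speed_of_sound Speed of sound in m/s (default 1540).
#' @param center_frequency Transmit center frequency in Hz (default 20 MHz).
#' @param sampling_frequency Sampling frequency in Hz (default 125 MHz,
#'   carried as metadata).
#'
#' @return An object of class \code{acoustic_grid}.
#' @export
acoustic_grid <- function(n_rows = 203L, n_cols = 203L,
                          pixel_size = 4.9e-6,
                          pixel_size_axial = pixel_size,
                          pixel_size_lateral = pixel_size,
                          speed_of_sound = 1540,
                          center_frequency = 20e6,
                          sampling_frequency = 125e6) {
  vals <- c(n_rows = n_rows, n_cols = n_cols,
            pixel_size_axial = pixel_size_axial,
            pixel_size_lateral = pixel_size_lateral,
            speed_of_sound = speed_of_sound,
            center_frequency = center_frequency,
            sampling_frequency = sampling_frequency)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all acoustic_grid quantities must be finite and strictly positive")
  }
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    pixel_size_axial = pixel_size_axial,
    pixel_size_lateral = pixel_size_lateral,
    speed_of_sound = speed_of_sound,
    center_frequency = center_frequency,
    sampling_frequency = sampling_frequency
  ), class = "acoustic_grid")
}

#' @export
print.acoustic_grid <- function(x, ...) {
  cat(sprintf("<acoustic_grid> %d x %d px, pixel %.3g x %.3g um\n",
              x$n_rows, x$n_cols,
              x$pixel_size_axial * 1e6, x$pixel_size_lateral * 1e6))
  cat(sprintf("  c = %g m/s, f0 = %g MHz, lambda = %.3g um\n",
              x$speed_of_sound, x$center_frequency / 1e6,
              wavelength(x) * 1e6))
  cat(sprintf("  field of view: %.4g x %.4g mm\n",
              x$n_rows * x$pixel_size_axial * 1e3,
              x$n_cols * x$pixel_size_lateral * 1e3))
  invisible(x)
}

#' Ultrasound wavelength of a grid
#'
#' @param grid An \code{\link{acoustic_grid}}.
#' @return Wavelength \code{speed_of_sound / center_frequency} in meters.
#' @export
#' @examples
#' wavelength(acoustic_grid())  # 77 um at 20 MHz in soft tissue
wavelength <- function(grid) {
  stopifnot(inherits(grid, "acoustic_grid"))
  grid$speed_of_sound / grid$center_frequency
}

#' Field-of-view area in mm^2
#'
#' @param grid An \code{\link{acoustic_grid}}.
#' @return Implied field-of-view area (n_rows * pixel_axial) x
#'   (n_cols * pixel_lateral), in mm^2. The grid dimensions are authoritative:
#'   a 203 x 203 grid at 4.9 um spans 0.9947 mm per side, reported as such.
#' @export
fov_area_mm2 <- function(grid) {
  stopifnot(inherits(grid, "acoustic_grid"))
  (grid$n_rows * grid$pixel_size_axial * 1e3) *
    (grid$n_cols * grid$pixel_size_lateral * 1e3)
}

#' Convert microbubble concentration between per-mm^2 and per-wavelength^2
#'
#' Concentrations are often quoted per square wavelength to compare systems
#' at different frequencies: 300 MBs/mm^2 at 20 MHz (lambda = 77 um) is
#' 1.8 MBs/lambda^2.
#'
#' @param conc_per_mm2 Concentration in MBs/mm^2 (non-negative).
#' @param conc_per_lambda2 Concentration in MBs/lambda^2 (non-negative).
#' @param grid An \code{\link{acoustic_grid}}.
#' @return The converted concentration (full precision; round for reporting).
#' @export
concentration_to_per_lambda2 <- function(conc_per_mm2, grid) {
  stopifnot(inherits(grid, "acoustic_grid"))
  if (any(conc_per_mm2 < 0)) stop("concentration must be non-negative")
  lambda_mm <- wavelength(grid) * 1e3
  conc_per_mm2 * lambda_mm^2
}

#' @rdname concentration_to_per_lambda2
#' @export
concentration_to_per_mm2 <- function(conc_per_lambda2, grid) {
  stopifnot(inherits(grid, "acoustic_grid"))
  if (any(conc_per_lambda2 < 0)) stop("concentration must be non-negative")
  lambda_mm <- wavelength(grid) * 1e3
  conc_per_lambda2 / lambda_mm^2
}

#' Express a pixel distance as a fraction of the wavelength
#'
#' Used to report localization tolerances and vessel separations in
#' wavelength units, e.g. a 5-pixel tolerance at 4.9 um pixels and 20 MHz is
#' 0.32 lambda.
#'
#' @param n_pixels Number of pixels (non-negative; may be fractional).
#' @param grid An \code{\link{acoustic_grid}}.
#' @param axis Which pixel size applies, \code{"axial"} or \code{"lateral"}.
#' @return Dimensionless wavelength fraction \code{n_pixels * pixel_size /
#'   lambda}.
#' @export
pixels_to_lambda <- function(n_pixels, grid, axis = c("axial", "lateral")) {
  stopifnot(inherits(grid, "acoustic_grid"))
  if (any(n_pixels < 0)) stop("n_pixels must be non-negative")
  axis <- match.arg(axis)
  px <- if (axis == "axial") grid$pixel_size_axial else grid$pixel_size_lateral
  n_pixels * px / wavelength(grid)
}

#' Real-time processing pixel budget
#'
#' For a display updating every \code{frame_period} seconds, the number of
#' image pixels that can be processed per frame is limited by the per-pixel
#' network inference cost plus the per-pixel, per-angle beamforming cost. At
#' a 10 Hz display with 2.38 us/pixel inference, 40 ns/pixel/angle
#' beamforming and 9 compounding angles the budget is 36496 pixels
#' (about 191 x 191).
#'
#' @param frame_period Time available per displayed frame, seconds.
#' @param dl_cost_per_pixel Network inference cost, seconds per pixel
#'   (default 2.38e-6).
#' @param beamform_cost_per_pixel_angle Beamforming cost, seconds per pixel
#'   per compounding angle (default 40e-9).
#' @param n_angles Number of compounding angles (default 9).
#' @return \code{realtime_budget}: the maximum integer pixel count (floor).
#'   \code{frame_time}: exact processing time in seconds for
#'   \code{n_pixels} pixels.
#' @export
realtime_budget <- function(frame_period,
                            dl_cost_per_pixel = 2.38e-6,
                            beamform_cost_per_pixel_angle = 40e-9,
                            n_angles = 9L) {
  .check_costs(frame_period, dl_cost_per_pixel, beamform_cost_per_pixel_angle)
  per_pixel <- dl_cost_per_pixel + n_angles * beamform_cost_per_pixel_angle
  as.integer(floor(frame_period / per_pixel))
}

#' @rdname realtime_budget
#' @param n_pixels Number of pixels processed per frame (non-negative).
#' @export
frame_time <- function(n_pixels,
                       dl_cost_per_pixel = 2.38e-6,
                       beamform_cost_per_pixel_angle = 40e-9,
                       n_angles = 9L) {
  .check_costs(1, dl_cost_per_pixel, beamform_cost_per_pixel_angle)
  if (any(n_pixels < 0)) stop("n_pixels must be non-negative")
  n_pixels * (dl_cost_per_pixel + n_angles * beamform_cost_per_pixel_angle)
}

.check_costs <- function(frame_period, dl_cost, bf_cost) {
  if (frame_period <= 0 || dl_cost <= 0 || bf_cost <= 0) {
    stop("frame period and per-pixel costs must be strictly positive")
  }
  invisible(TRUE)
}
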