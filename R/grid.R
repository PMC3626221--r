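#' @useDynLib ctrecon, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm fft
NULL

#' Square attenuation image
#'
#' Container for a square 2D map of linear attenuation coefficients
#' \eqn{\mu} (unitless per length).  Rows are image rows, top row first;
#' the image is centred at the physical origin with pixel width
#' `pixel_size` in arbitrary length units.
#'
#' @param values numeric square matrix of attenuation coefficients.
#' @param pixel_size positive pixel side length (default 1).
#' @return An object of class `image_grid` with fields `values`,
#'   `side_px` and `pixel_size`.
#' @examples
#' g <- image_grid(matrix(0, 8, 8))
#' g$side_px
#' @export
image_grid <- function(values, pixel_size = 1.0) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values) || nrow(values) < 1)
    stop("image must be a square matrix with side >= 1")
  if (!all(is.finite(values)))
    stop("image values must be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a positive scalar")
  structure(list(values = values, side_px = nrow(values),
                 pixel_size = pixel_size),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid %dx%d, pixel_size %g, range [%g, %g]>\n",
              x$side_px, x$side_px, x$pixel_size,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Parallel-beam projection geometry
#'
#' View angles are beam inclinations \eqn{\theta} in degrees on
#' \eqn{[0, 180)}; a ray at angle \eqn{\theta} and signed detector offset
#' `t` satisfies \eqn{t = x\cos\theta + y\sin\theta}.  Detector bins are
#' centred at `t = (k - (n_detectors - 1)/2) * detector_spacing` for
#' `k = 0, ..., n_detectors - 1`.
#'
#' @param angles_deg strictly increasing view angles in degrees, each in
#'   `[0, 180)`.
#' @param n_detectors number of detector bins per view.
#' @param detector_spacing detector bin pitch (same units as pixel size).
#' @return An object of class `projection_geometry`.
#' @export
projection_geometry <- function(angles_deg, n_detectors,
                                detector_spacing = 1.0) {
  angles_deg <- as.numeric(angles_deg)
  if (length(angles_deg) < 1)
    stop("at least one view angle is required")
  if (any(angles_deg < 0 | angles_deg >= 180))
    stop("view angles must lie in [0, 180)")
  if (is.unsorted(angles_deg, strictly = TRUE))
    stop("view angles must be strictly increasing")
  if (n_detectors < 1) stop("n_detectors must be >= 1")
  if (detector_spacing <= 0) stop("detector_spacing must be positive")
  structure(list(angles_deg = angles_deg,
                 n_detectors = as.integer(n_detectors),
                 detector_spacing = detector_spacing),
            class = "projection_geometry")
}

#' Uniformly spaced view angles over 180 degrees
#'
#' @param n_views number of views; angles are `(0:(n_views-1)) * 180 / n_views`.
#' @param n_detectors,detector_spacing passed to [projection_geometry()].
#' @export
uniform_geometry <- function(n_views, n_detectors, detector_spacing = 1.0) {
  projection_geometry((seq_len(n_views) - 1) * 180 / n_views,
                      n_detectors, detector_spacing)
}

#' Sinogram container
#'
#' @param values matrix of line integrals, one row per view, one column
#'   per detector bin.
#' @param geometry the [projection_geometry()] the data were acquired with.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, geometry) {
  values <- as.matrix(values)
  stopifnot(inherits(geometry, "projection_geometry"))
  if (nrow(values) != length(geometry$angles_deg) ||
      ncol(values) != geometry$n_detectors)
    stop("sinogram shape does not match geometry")
  if (!all(is.finite(values))) stop("sinogram values must be finite")
  structure(list(values = values, geometry = geometry), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram %d views x %d detectors>\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Row-major flattening used throughout: flat index = (row - 1) * side + col.
flatten_image <- function(m) as.vector(t(m))

unflatten_image <- function(v, side) matrix(v, nrow = side, byrow = TRUE)

#' Reconstruction result
#'
#' @param image the reconstructed [image_grid()].
#' @param trace per-iteration diagnostic (residual or objective values).
#' @param method solver label.
#' @param iterations number of iterations run.
#' @param converged logical convergence flag.
#' @export
recon_result <- function(image, trace, method, iterations,
                         converged = NA) {
  structure(list(image = image, trace = trace, method = method,
                 iterations = iterations, converged = converged),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result %s: %d iterations, final trace %g>\n",
              x$method, x$iterations,
              if (length(x$trace)) x$trace[length(x$trace)] else NA_real_))
  invisible(x)
}
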