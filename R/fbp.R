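#' Band-limited ramp filter kernels
#'
#' Spatial-domain kernels for the ramp (high-pass) filter used by
#' filtered backprojection, sampled at the detector pitch \eqn{\Delta}.
#'
#' * `ram-lak`: \eqn{h(0) = 1/(4\Delta^2)}, \eqn{h(k) = -1/(\pi k \Delta)^2}
#'   for odd \eqn{k}, and 0 for even \eqn{k \neq 0} — the band-limited
#'   ideal ramp.
#' * `shepp-logan`: the ramp apodized by a sinc window in frequency,
#'   whose spatial samples have the closed form
#'   \eqn{h(k) = -2/(\pi^2 \Delta^2 (4k^2 - 1))}.
#'
#' @param kind `"ram-lak"` or `"shepp-logan"`.
#' @param n_taps odd kernel length.
#' @param detector_spacing detector pitch \eqn{\Delta}.
#' @return An object of class `ramp_filter` with the symmetric `kernel`
#'   (length `n_taps`, centre tap at index `(n_taps + 1)/2`).
#' @examples
#' f <- build_ramp_filter("ram-lak", 5, 1)
#' f$kernel  # 0, -1/pi^2, 0.25, -1/pi^2, 0
#' @export
build_ramp_filter <- function(kind = c("ram-lak", "shepp-logan"),
                              n_taps, detector_spacing = 1.0) {
  kind <- match.arg(kind)
  if (n_taps %% 2 != 1 || n_taps < 1) stop("n_taps must be odd and positive")
  stopifnot(detector_spacing > 0)
  K <- (n_taps - 1) / 2
  k <- -K:K
  d <- detector_spacing
  h <- switch(kind,
    "ram-lak" = ifelse(k == 0, 1 / (4 * d^2),
                       ifelse(k %% 2 != 0, -1 / (pi * k * d)^2, 0)),
    "shepp-logan" = -2 / (pi^2 * d^2 * (4 * k^2 - 1)))
  structure(list(kind = kind, n_taps = as.integer(n_taps),
                 detector_spacing = d, kernel = h, offsets = k),
            class = "ramp_filter")
}

# FFT linear convolution of each sinogram row with the ramp kernel,
# zero-padded to the next power of two >= 2 * n_det + n_taps.  The full
# convolution support is kept (columns extend K = (n_taps-1)/2 bins past
# each end of the detector array): the ramp response has slowly decaying
# negative tails outside the measured window, and truncating them biases
# the image periphery upward.
filter_views <- function(P, filt) {
  n_det <- ncol(P)
  n_taps <- filt$n_taps
  K <- (n_taps - 1) / 2
  L <- 2^ceiling(log2(2 * n_det + n_taps))
  hpad <- numeric(L)
  hpad[1:n_taps] <- filt$kernel
  H <- fft(hpad)
  Ppad <- matrix(0, nrow(P), L)
  Ppad[, 1:n_det] <- P
  Q <- t(apply(Ppad, 1, function(row) Re(fft(fft(row) * H, inverse = TRUE)) / L))
  # column c of the result corresponds to detector bin index c - K
  list(Q = Q[, 1:(n_det + 2 * K), drop = FALSE] * filt$detector_spacing,
       K = K)
}

#' Filtered backprojection reconstruction
#'
#' Ramp-filters each view (spatial convolution with the chosen kernel,
#' times the detector pitch) and backprojects with linear interpolation
#' in the detector coordinate, scaling by \eqn{\pi / n_{views}} to
#' discretize the angular integral over \eqn{[0, \pi)}.
#'
#' @param sino a [sinogram()].
#' @param side_px output image side in pixels.
#' @param pixel_size output pixel size.
#' @param filter a [build_ramp_filter()] object, or `NULL` for a default
#'   Ram-Lak kernel of length `2 * n_detectors - 1`.
#' @return An [image_grid()].
#' @export
fbp_reconstruct <- function(sino, side_px, pixel_size = 1.0, filter = NULL) {
  stopifnot(inherits(sino, "sinogram"))
  geom <- sino$geometry
  n_views <- length(geom$angles_deg)
  if (n_views < 1 || geom$n_detectors < 1) stop("empty sinogram")
  if (is.null(filter))
    filter <- build_ramp_filter("ram-lak", 2L * geom$n_detectors - 1L,
                                geom$detector_spacing)
  fv <- filter_views(sino$values, filter)
  Q <- fv$Q
  K <- fv$K

  s <- side_px
  xc <- ((seq_len(s)) - (s + 1) / 2) * pixel_size
  yc <- ((s + 1) / 2 - seq_len(s)) * pixel_size
  X <- matrix(xc, s, s, byrow = TRUE)
  Y <- matrix(yc, s, s)
  n_det <- geom$n_detectors
  d <- geom$detector_spacing
  img <- matrix(0, s, s)
  for (v in seq_len(n_views)) {
    th <- geom$angles_deg[v] * pi / 180
    tq <- X * cos(th) + Y * sin(th)
    # fractional column index into the extended filtered view
    fk <- tq / d + (n_det - 1) / 2 + 1 + K
    k0 <- floor(fk)
    w <- fk - k0
    q <- Q[v, ]
    nq <- length(q)
    val <- matrix(0, s, s)
    in0 <- k0 >= 1 & k0 <= nq
    in1 <- (k0 + 1) >= 1 & (k0 + 1) <= nq
    val[in0] <- (1 - w[in0]) * q[k0[in0]]
    val[in1] <- val[in1] + w[in1] * q[k0[in1] + 1]
    img <- img + val
  }
  image_grid(img * pi / n_views, pixel_size)
}
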