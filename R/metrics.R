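#' Relative root mean square error
#'
#' \eqn{RRMSE = \|y - y_{ref}\|_2 / \|y_{ref}\|_2}.
#'
#' @param y,y_ref images ([image_grid()] or matrices) of equal shape.
#' @return Nonnegative scalar.
#' @export
rrmse <- function(y, y_ref) {
  a <- as_values(y); b <- as_values(y_ref)
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop("reference image has zero norm")
  sqrt(sum((a - b)^2)) / nb
}

#' Streak indicator
#'
#' Total variation of the difference between a reconstruction and its
#' reference, \eqn{SI = TV(y - y_{ref})}, using the exact (unsmoothed)
#' isotropic TV with the same forward-difference convention as
#' [tv_norm()].  Lower values indicate fewer streaking artifacts.
#'
#' @inheritParams rrmse
#' @return Nonnegative scalar.
#' @export
streak_indicator <- function(y, y_ref) {
  a <- as_values(y); b <- as_values(y_ref)
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  tv_norm(a - b, xi = 0)
}

#' SSIM configuration
#'
#' Standard reference settings: an 11 x 11 Gaussian window with
#' \eqn{\sigma = 1.5} (normalized to unit mass), stabilizers
#' \eqn{C_1 = (K_1 L)^2}, \eqn{C_2 = (K_2 L)^2}, \eqn{C_3 = C_2/2} with
#' \eqn{K_1 = 0.01}, \eqn{K_2 = 0.03} and data range \eqn{L}, and mean
#' pooling of the SSIM map.  `L = NULL` takes the data range of the
#' reference image.
#'
#' @param window_size odd window side (default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @param K1,K2 stabilizer fractions of the data range.
#' @param L data range, or `NULL` to use the reference's range.
#' @return An object of class `ssim_config`.
#' @export
ssim_config <- function(window_size = 11, sigma = 1.5,
                        K1 = 0.01, K2 = 0.03, L = NULL) {
  stopifnot(window_size %% 2 == 1, window_size >= 3, sigma > 0,
            K1 > 0, K2 > 0)
  structure(list(window_size = as.integer(window_size), sigma = sigma,
                 K1 = K1, K2 = K2, L = L),
            class = "ssim_config")
}

gaussian_window <- function(size, sigma) {
  k <- seq_len(size) - (size + 1) / 2
  w <- exp(-k^2 / (2 * sigma^2))
  w / sum(w)   # separable; the 2D window then also has unit mass
}

# valid-mode separable window filtering: F X F^T with F the banded
# (N - size + 1) x N sliding-window matrix
window_filter_matrix <- function(N, w) {
  L <- length(w)
  M <- N - L + 1
  if (M < 1) stop("image smaller than the SSIM window")
  F <- matrix(0, M, N)
  for (i in seq_len(M)) F[i, i:(i + L - 1)] <- w
  F
}

#' Structural similarity index
#'
#' Mean-pooled local SSIM over sliding windows: for each window the
#' luminance, contrast and structure similarities
#' \deqn{l = \frac{2\mu_\rho\mu_t + C_1}{\mu_\rho^2 + \mu_t^2 + C_1},\;
#'       c = \frac{2\sigma_\rho\sigma_t + C_2}{\sigma_\rho^2 + \sigma_t^2 + C_2},\;
#'       s = \frac{\sigma_{\rho t} + C_3}{\sigma_\rho\sigma_t + C_3}}
#' are multiplied and the map is averaged.  Local moments are
#' Gaussian-window weighted; with \eqn{C_3 = C_2/2} the product reduces
#' to the familiar two-term SSIM.
#'
#' @inheritParams rrmse
#' @param cfg a [ssim_config()].
#' @return Scalar in \eqn{[-1, 1]}.
#' @export
ssim <- function(y, y_ref, cfg = ssim_config()) {
  a <- as_values(y); b <- as_values(y_ref)
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  L <- if (is.null(cfg$L)) diff(range(b)) else cfg$L
  if (L <= 0) L <- 1
  C1 <- (cfg$K1 * L)^2
  C2 <- (cfg$K2 * L)^2
  C3 <- C2 / 2
  w <- gaussian_window(cfg$window_size, cfg$sigma)
  Fr <- window_filter_matrix(nrow(a), w)
  Fc <- window_filter_matrix(ncol(a), w)
  filt <- function(m) Fr %*% m %*% t(Fc)
  mu_a <- filt(a); mu_b <- filt(b)
  va <- pmax(filt(a * a) - mu_a^2, 0)
  vb <- pmax(filt(b * b) - mu_b^2, 0)
  cab <- filt(a * b) - mu_a * mu_b
  sa <- sqrt(va); sb <- sqrt(vb)
  lum <- (2 * mu_a * mu_b + C1) / (mu_a^2 + mu_b^2 + C1)
  con <- (2 * sa * sb + C2) / (va + vb + C2)
  str <- (cab + C3) / (sa * sb + C3)
  mean(lum * con * str)
}

#' Evaluate a reconstruction against a reference
#'
#' @inheritParams rrmse
#' @param metrics character vector from `c("rrmse", "si", "ssim")`.
#' @param ssim_cfg a [ssim_config()].
#' @return Named numeric vector of the requested metrics.
#' @export
evaluate_recon <- function(y, y_ref, metrics = c("rrmse", "si", "ssim"),
                           ssim_cfg = ssim_config()) {
  out <- c()
  if ("rrmse" %in% metrics) out["rrmse"] <- rrmse(y, y_ref)
  if ("si" %in% metrics) out["si"] <- streak_indicator(y, y_ref)
  if ("ssim" %in% metrics) out["ssim"] <- ssim(y, y_ref, ssim_cfg)
  out
}
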