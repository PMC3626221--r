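# Orthonormal periodic discrete wavelet transforms.
#
# The analysis step for a signal of even length N is
#   a_j = sum_k h_k x_{(2j + k) mod N},   d_j = sum_k g_k x_{(2j + k) mod N}
# with the quadrature mirror highpass g_k = (-1)^k h_{L-1-k}.  Stacking
# [a; d] gives an orthogonal N x N step matrix; synthesis is its
# transpose.  2D transforms apply the step along rows and columns
# (W X W^T) and recurse on the approximation quadrant (Mallat layout).

wavelet_filters <- list(
  haar = c(1, 1) / sqrt(2),
  # Daubechies extremal-phase filter with 4 vanishing moments (8 taps)
  db4 = c(0.230377813308855230, 0.714846570552541500,
          0.630880767929590400, -0.027983769416983850,
          -0.187034811718881140, 0.030841381835986965,
          0.032883011666982945, -0.010597401784997278)
)

dwt_step_matrix <- function(N, h) {
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  W <- matrix(0, N, N)
  half <- N / 2
  for (j in seq_len(half)) {
    for (k in seq_len(L)) {
      col <- (2 * (j - 1) + (k - 1)) %% N + 1
      W[j, col] <- W[j, col] + h[k]
      W[half + j, col] <- W[half + j, col] + g[k]
    }
  }
  W
}

#' Orthonormal 2D wavelet operator
#'
#' Builds the sparsity transform \eqn{\Phi} used by the compressed
#' sensing solver: a multi-level periodic orthonormal 2D discrete
#' wavelet transform.  Orthonormality gives \eqn{\|\Phi\mu\|_2 =
#' \|\mu\|_2} and \eqn{\Phi^T = \Phi^{-1}}, which the solver exploits
#' for the \eqn{\ell_1}-term gradient.
#'
#' Images whose side is not a power of two are zero-padded (bottom/right)
#' to the next power of two inside the operator only; the requested
#' decomposition depth is reduced if needed so every level has an even
#' size of at least 2.
#'
#' @param side image side in pixels.
#' @param family `"db4"` (default) or `"haar"`.
#' @param levels requested decomposition levels (default 4).
#' @return An object of class `wavelet_operator`.
#' @export
wavelet_operator <- function(side, family = c("db4", "haar"), levels = 4) {
  family <- match.arg(family)
  if (side < 1) stop("side must be positive")
  h <- wavelet_filters[[family]]
  pad_side <- 2^ceiling(log2(max(side, 2)))
  max_lev <- floor(log2(pad_side)) - 1
  lev <- max(1, min(levels, max_lev))
  sizes <- pad_side / 2^(seq_len(lev) - 1)
  steps <- lapply(sizes, dwt_step_matrix, h = h)
  structure(list(side = side, pad_side = pad_side, family = family,
                 levels = lev, sizes = sizes, steps = steps,
                 n_coeffs = pad_side^2),
            class = "wavelet_operator")
}

#' Forward and inverse wavelet transform
#'
#' `wavelet_forward` maps an image matrix to its coefficient matrix
#' (Mallat layout, padded side); `wavelet_inverse` is the exact inverse,
#' returning the image cropped back to the operator's side.
#'
#' @param op a [wavelet_operator()].
#' @param m image matrix (`side x side`) or coefficient matrix
#'   (`pad_side x pad_side`).
#' @return A matrix.
#' @export
wavelet_forward <- function(op, m) {
  stopifnot(inherits(op, "wavelet_operator"))
  if (nrow(m) != op$side || ncol(m) != op$side)
    stop("image side does not match the wavelet operator")
  X <- matrix(0, op$pad_side, op$pad_side)
  X[seq_len(op$side), seq_len(op$side)] <- m
  for (l in seq_len(op$levels)) {
    N <- op$sizes[l]
    W <- op$steps[[l]]
    X[1:N, 1:N] <- W %*% X[1:N, 1:N, drop = FALSE] %*% t(W)
  }
  X
}

#' @rdname wavelet_forward
#' @export
wavelet_inverse <- function(op, m) {
  stopifnot(inherits(op, "wavelet_operator"))
  if (nrow(m) != op$pad_side || ncol(m) != op$pad_side)
    stop("coefficient side does not match the wavelet operator")
  X <- m
  for (l in rev(seq_len(op$levels))) {
    N <- op$sizes[l]
    W <- op$steps[[l]]
    X[1:N, 1:N] <- t(W) %*% X[1:N, 1:N, drop = FALSE] %*% W
  }
  X[seq_len(op$side), seq_len(op$side), drop = FALSE]
}
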