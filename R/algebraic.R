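#' Configuration for the algebraic solvers
#'
#' @param relaxation relaxation parameter \eqn{\lambda} in (0, 2);
#'   the classical choice, used by default, is 1.
#' @param n_iterations number of full sweeps (ART) or simultaneous
#'   iterations (SART).  Defaults follow common sparse-view practice:
#'   30 for ART and 150 for SART.
#' @param x0 optional initial [image_grid()] (default: zero image).
#' @param nonneg clamp the iterate to be nonnegative after each
#'   sweep/iteration (off by default).
#' @return An object of class `algebraic_config`.
#' @export
algebraic_config <- function(relaxation = 1.0, n_iterations = NULL,
                             x0 = NULL, nonneg = FALSE) {
  if (relaxation <= 0 || relaxation >= 2)
    stop("relaxation must lie in (0, 2)")
  if (!is.null(n_iterations) && n_iterations < 1)
    stop("n_iterations must be positive")
  structure(list(relaxation = relaxation, n_iterations = n_iterations,
                 x0 = x0, nonneg = isTRUE(nonneg)),
            class = "algebraic_config")
}

init_vec <- function(cfg, A) {
  if (is.null(cfg$x0)) numeric(ncol(A$A)) else flatten_image(cfg$x0$values)
}

#' ART (Kaczmarz) reconstruction
#'
#' Solves \eqn{y = A\mu} by cyclic row projections: each sweep visits the
#' rays in order \eqn{i = 1, \dots, m} and applies
#' \deqn{x \leftarrow x + \lambda \frac{b_i - \langle a_i, x\rangle}{\|a_i\|^2} a_i.}
#' Rays with empty rows (missing the image) are skipped.  The residual
#' 2-norm \eqn{\|Ax - b\|_2} is recorded after every sweep.
#'
#' @param A a `system_matrix`.
#' @param y a [sinogram()].
#' @param cfg an [algebraic_config()]; `n_iterations` defaults to 30.
#' @return A [recon_result()] with the residual trace.
#' @export
art_reconstruct <- function(A, y, cfg = algebraic_config()) {
  stopifnot(inherits(A, "system_matrix"), inherits(y, "sinogram"))
  if (all(A$row_sums == 0)) stop("system matrix is identically zero")
  n_it <- if (is.null(cfg$n_iterations)) 30L else as.integer(cfg$n_iterations)
  R <- as(A$A, "RsparseMatrix")
  b <- sino_to_vec(y)
  if (length(b) != nrow(A$A)) stop("sinogram shape does not match the system matrix")
  out <- .art_sweeps(R@p, R@j, R@x, b, init_vec(cfg, A),
                     cfg$relaxation, n_it, cfg$nonneg)
  recon_result(image_grid(unflatten_image(out$x, A$side_px), A$pixel_size),
               out$residual, "art", n_it)
}

#' SART reconstruction
#'
#' Simultaneous algebraic reconstruction: every ray contributes to each
#' update,
#' \deqn{x \leftarrow x + \lambda\, V^{-1} A^T W^{-1} (b - Ax),}
#' where \eqn{W = \mathrm{diag}(\|a_i\|_1)} holds the row sums (applied
#' to the residual) and \eqn{V = \mathrm{diag}(\|a_j\|_1)} the column
#' sums (applied after the backprojection).  Rays with zero row sum and
#' pixels with zero column sum are excluded from the update.  The
#' residual 2-norm is recorded after every iteration.
#'
#' @inheritParams art_reconstruct
#' @param cfg an [algebraic_config()]; `n_iterations` defaults to 150.
#' @return A [recon_result()] with the residual trace.
#' @export
sart_reconstruct <- function(A, y, cfg = algebraic_config()) {
  stopifnot(inherits(A, "system_matrix"), inherits(y, "sinogram"))
  n_it <- if (is.null(cfg$n_iterations)) 150L else as.integer(cfg$n_iterations)
  M <- A$A
  b <- sino_to_vec(y)
  if (length(b) != nrow(M)) stop("sinogram shape does not match the system matrix")
  wr <- A$row_sums
  wc <- A$col_sums
  row_ok <- wr > 0
  col_ok <- wc > 0
  inv_r <- ifelse(row_ok, 1 / wr, 0)
  inv_c <- ifelse(col_ok, 1 / wc, 0)
  x <- init_vec(cfg, A)
  resid <- numeric(n_it)
  for (it in seq_len(n_it)) {
    r <- b - as.numeric(M %*% x)
    upd <- as.numeric(Matrix::crossprod(M, r * inv_r)) * inv_c
    x <- x + cfg$relaxation * upd
    if (cfg$nonneg) x[x < 0] <- 0
    resid[it] <- sqrt(sum((as.numeric(M %*% x) - b)^2))
  }
  recon_result(image_grid(unflatten_image(x, A$side_px), A$pixel_size),
               resid, "sart", n_it)
}
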