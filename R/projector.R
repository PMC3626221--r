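#' Build the X-ray system matrix
#'
#' Computes the sparse matrix \eqn{A} whose entry \eqn{A_{ji}} is the
#' exact intersection (chord) length of ray \eqn{j} with pixel \eqn{i}
#' under the indicator-function pixel basis, so that forward projection
#' is the matrix product \eqn{y = A\mu}.  Rays are ordered view-major
#' (all detector bins of view 1, then view 2, ...); pixels are flattened
#' row-major.  Rays that miss the image square yield empty rows.
#'
#' @param grid an [image_grid()] (only its side and pixel size are used).
#' @param geom a [projection_geometry()].
#' @return An object of class `system_matrix`: a list with the
#'   `Matrix::dgCMatrix` `A` (m x n), cached `row_sums` and `col_sums`
#'   (1-norms), and the originating `grid`/`geom` descriptors.
#' @examples
#' g <- image_grid(matrix(1, 4, 4))
#' A <- build_system_matrix(g, uniform_geometry(6, 4))
#' dim(A$A)
#' @export
build_system_matrix <- function(grid, geom) {
  stopifnot(inherits(grid, "image_grid"), inherits(geom, "projection_geometry"))
  trip <- .trace_system_matrix(grid$side_px, grid$pixel_size,
                               geom$angles_deg * pi / 180,
                               geom$n_detectors, geom$detector_spacing)
  m <- length(geom$angles_deg) * geom$n_detectors
  n <- grid$side_px^2
  A <- Matrix::sparseMatrix(i = trip$i + 1L, j = trip$j + 1L, x = trip$x,
                            dims = c(m, n))
  structure(list(A = A,
                 row_sums = Matrix::rowSums(A),
                 col_sums = Matrix::colSums(A),
                 side_px = grid$side_px,
                 pixel_size = grid$pixel_size,
                 geometry = geom),
            class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf("<system_matrix %d x %d, %d nonzeros>\n",
              nrow(x$A), ncol(x$A), length(x$A@x)))
  invisible(x)
}

#' Forward projection
#'
#' Applies the system matrix to an image: \eqn{y = A\mu}.
#'
#' @param A a `system_matrix` built for an image of the same side.
#' @param grid the [image_grid()] to project.
#' @return A [sinogram()].
#' @export
forward_project <- function(A, grid) {
  stopifnot(inherits(A, "system_matrix"), inherits(grid, "image_grid"))
  if (grid$side_px != A$side_px)
    stop("image side does not match the system matrix")
  y <- as.numeric(A$A %*% flatten_image(grid$values))
  sinogram(matrix(y, nrow = length(A$geometry$angles_deg), byrow = TRUE),
           A$geometry)
}

#' Backprojection (adjoint of forward projection)
#'
#' Computes \eqn{A^T y} reshaped to the image grid.  This is the exact
#' adjoint of [forward_project()], as required by gradient-based solvers.
#'
#' @param A a `system_matrix`.
#' @param sino a [sinogram()] with matching geometry.
#' @return An [image_grid()].
#' @export
back_project <- function(A, sino) {
  stopifnot(inherits(A, "system_matrix"), inherits(sino, "sinogram"))
  y <- as.vector(t(sino$values))
  if (length(y) != nrow(A$A)) stop("sinogram shape does not match the system matrix")
  v <- as.numeric(Matrix::crossprod(A$A, y))
  image_grid(unflatten_image(v, A$side_px), A$pixel_size)
}

# Sinogram matrix <-> stacked ray vector (view-major), shared by solvers.
sino_to_vec <- function(sino) as.vector(t(sino$values))
vec_to_sino <- function(v, geom) {
  sinogram(matrix(v, nrow = length(geom$angles_deg), byrow = TRUE), geom)
}
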