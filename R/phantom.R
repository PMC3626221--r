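#' Phantom specification
#'
#' Describes a piecewise-constant test object as a background value plus
#' a list of additive primitives (discs, ellipses, rectangles).  A pixel
#' takes the background value plus the sum of the values of all
#' primitives whose region contains the pixel centre (centre-point
#' membership, no anti-aliasing).  Coordinates are physical: the image is
#' centred at the origin and spans `[-side_px*pixel_size/2, +...]` in x
#' and y, with x to the right and y upwards.
#'
#' Primitive formats (all values additive):
#' * `list(shape = "disc", center = c(x, y), radius = r, value = v)`
#' * `list(shape = "ellipse", center, semi_axes = c(a, b), rotation_deg, value)`
#' * `list(shape = "rect", center, width, height, rotation_deg, value)`
#'
#' @param side_px image side in pixels.
#' @param primitives list of primitive descriptions.
#' @param background background attenuation value.
#' @param pixel_size pixel side length.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(side_px, primitives = list(), background = 0,
                         pixel_size = 1.0) {
  stopifnot(side_px >= 1, pixel_size > 0, is.finite(background))
  half <- side_px * pixel_size / 2
  for (p in primitives) {
    if (!p$shape %in% c("disc", "ellipse", "rect"))
      stop("unknown primitive shape: ", p$shape)
    ext <- switch(p$shape,
                  disc = p$radius,
                  ellipse = max(p$semi_axes),
                  rect = sqrt(p$width^2 + p$height^2) / 2)
    if (any(abs(p$center) + ext > half + 1e-9))
      stop("primitive extends outside the image square")
  }
  structure(list(side_px = as.integer(side_px), primitives = primitives,
                 background = background, pixel_size = pixel_size),
            class = "phantom_spec")
}

#' Rasterize a phantom
#'
#' @param spec a [phantom_spec()].
#' @return An [image_grid()]; generation is deterministic.
#' @examples
#' sp <- phantom_spec(32, list(list(shape = "disc", center = c(0, 0),
#'                                  radius = 8, value = 1)))
#' table(generate_phantom(sp)$values)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$side_px
  px <- spec$pixel_size
  # pixel-centre coordinates; row 1 is the top of the image (largest y)
  xc <- ((seq_len(s)) - (s + 1) / 2) * px
  yc <- ((s + 1) / 2 - seq_len(s)) * px
  X <- matrix(xc, s, s, byrow = TRUE)
  Y <- matrix(yc, s, s)
  img <- matrix(spec$background, s, s)
  for (p in spec$primitives) {
    dx <- X - p$center[1]
    dy <- Y - p$center[2]
    rot <- if (is.null(p$rotation_deg)) 0 else p$rotation_deg * pi / 180
    if (rot != 0) {
      u <- cos(rot) * dx + sin(rot) * dy
      v <- -sin(rot) * dx + cos(rot) * dy
    } else {
      u <- dx; v <- dy
    }
    inside <- switch(p$shape,
      disc = u^2 + v^2 <= p$radius^2,
      ellipse = (u / p$semi_axes[1])^2 + (v / p$semi_axes[2])^2 <= 1,
      rect = abs(u) <= p$width / 2 & abs(v) <= p$height / 2)
    img <- img + p$value * inside
  }
  image_grid(img, px)
}

#' Default evaluation phantom
#'
#' A 128 x 128 head-like phantom used by the package's benchmark suite:
#' a disc of value 0.2 and radius `0.45 * side` on a zero background,
#' four low-contrast disc inserts at additive contrasts 0.5, 0.1, 0.05
#' and 0.02, and a comb of five 2-pixel-wide bars emulating fine
#' (trabecular-like) structure.
#'
#' @param side_px image side in pixels (default 128).
#' @param pixel_size pixel side length.
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(side_px = 128, pixel_size = 1.0) {
  s <- side_px * pixel_size
  r_main <- 0.45 * s
  r_ins <- 0.07 * s
  contrasts <- c(0.5, 0.1, 0.05, 0.02)
  offs <- 0.22 * s
  centers <- list(c(-offs, offs), c(offs, offs), c(-offs, -offs), c(offs, -offs))
  prim <- list(list(shape = "disc", center = c(0, 0), radius = r_main,
                    value = 0.2))
  for (k in seq_along(contrasts))
    prim[[length(prim) + 1]] <- list(shape = "disc", center = centers[[k]],
                                     radius = r_ins, value = contrasts[k])
  # comb of thin vertical bars (2 px wide, spaced 4 px) at centre-bottom
  bar_w <- 2 * pixel_size
  bar_h <- 0.15 * s
  for (k in -2:2)
    prim[[length(prim) + 1]] <- list(shape = "rect",
                                     center = c(k * 4 * pixel_size, -0.05 * s),
                                     width = bar_w, height = bar_h,
                                     value = 0.3)
  phantom_spec(side_px, prim, background = 0, pixel_size = pixel_size)
}

#' Simulate projection data
#'
#' Computes the line integrals of an image over the given geometry,
#' i.e. `forward_project(build_system_matrix(grid, geom), grid)`.
#'
#' @param grid an [image_grid()].
#' @param geom a [projection_geometry()].
#' @param A optional pre-built `system_matrix` to reuse.
#' @return A [sinogram()].
#' @export
simulate_sinogram <- function(grid, geom, A = NULL) {
  if (is.null(A)) A <- build_system_matrix(grid, geom)
  forward_project(A, grid)
}

#' Additive Gaussian sinogram noise
#'
#' Draws i.i.d. Gaussian noise and rescales it so the realized relative
#' magnitude \eqn{\|e\|_2 / \|y\|_2} equals `relative_level` exactly,
#' making the contamination level deterministic in norm while the noise
#' pattern depends on the seed.
#'
#' @param sino a [sinogram()].
#' @param relative_level nonnegative target for \eqn{\|e\|_2/\|y\|_2}.
#' @param seed integer seed controlling the noise pattern.
#' @return A [sinogram()] with noise added.
#' @export
add_noise <- function(sino, relative_level, seed = 1L) {
  stopifnot(inherits(sino, "sinogram"), relative_level >= 0)
  if (relative_level == 0) return(sino)
  ynorm <- sqrt(sum(sino$values^2))
  if (ynorm == 0) stop("cannot scale noise relative to a zero sinogram")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  e <- matrix(rnorm(length(sino$values)), nrow = nrow(sino$values))
  e <- e * (relative_level * ynorm / sqrt(sum(e^2)))
  sinogram(sino$values + e, sino$geometry)
}

#' Uniform view decimation
#'
#' Keeps `n_keep` views at a uniform index stride starting at view 1,
#' emulating sparse-view acquisition from a densely sampled scan.  Kept
#' rows are copied bit-exactly; the returned geometry lists the kept
#' angles.
#'
#' @param sino a [sinogram()].
#' @param n_keep number of views to keep (`<= n_views`).
#' @return A [sinogram()] with `n_keep` views.
#' @export
decimate_views <- function(sino, n_keep) {
  stopifnot(inherits(sino, "sinogram"))
  n <- length(sino$geometry$angles_deg)
  if (n_keep > n) stop("n_keep exceeds the number of available views")
  if (n_keep < 1) stop("n_keep must be positive")
  idx <- floor((seq_len(n_keep) - 1) * n / n_keep) + 1L
  geom <- projection_geometry(sino$geometry$angles_deg[idx],
                              sino$geometry$n_detectors,
                              sino$geometry$detector_spacing)
  sinogram(sino$values[idx, , drop = FALSE], geom)
}
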