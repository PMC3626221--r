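#' Smoothed absolute value
#'
#' The \eqn{\ell_1}-type terms of the reconstruction objective use the
#' smooth surrogate \eqn{|x| \approx \sqrt{x^2 + \xi}} with a small
#' positive smoothing parameter \eqn{\xi}, whose derivative
#' \eqn{x/\sqrt{x^2+\xi}} is defined everywhere.
#'
#' @param x numeric scalar, vector or matrix.
#' @param xi positive smoothing parameter (default `1e-15`).
#' @return `smoothed_abs`: \eqn{\sqrt{x^2+\xi}} elementwise;
#'   `smoothed_abs_grad`: its derivative.
#' @export
smoothed_abs <- function(x, xi = 1e-15) {
  stopifnot(xi > 0)
  sqrt(x * x + xi)
}

#' @rdname smoothed_abs
#' @export
smoothed_abs_grad <- function(x, xi = 1e-15) {
  stopifnot(xi > 0)
  x / sqrt(x * x + xi)
}

as_values <- function(m) if (inherits(m, "image_grid")) m$values else as.matrix(m)

tv_diffs <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  dx <- cbind(m[, -1, drop = FALSE] - m[, -nc, drop = FALSE], numeric(nr))
  dy <- rbind(m[-1, , drop = FALSE] - m[-nr, , drop = FALSE], numeric(nc))
  list(dx = dx, dy = dy)
}

#' Isotropic total variation
#'
#' Discrete isotropic TV with forward differences and replicate
#' (Neumann) boundary handling — the difference past the last row or
#' column is zero:
#' \deqn{\|\mu\|_{TV} = \sum_{i,j} \sqrt{(\nabla_x\mu)^2_{ij} + (\nabla_y\mu)^2_{ij} + \xi}.}
#' With `xi = 0` this is the exact TV (used for reporting and for the
#' streak indicator); the solver uses `xi > 0` so the objective is
#' smooth.
#'
#' @param m an [image_grid()] or plain matrix.
#' @param xi nonnegative smoothing parameter.
#' @return Scalar TV value.
#' @export
tv_norm <- function(m, xi = 0) {
  stopifnot(xi >= 0)
  d <- tv_diffs(as_values(m))
  sum(sqrt(d$dx^2 + d$dy^2 + xi))
}

#' Gradient of the smoothed total variation
#'
#' Negative discrete divergence of the normalized gradient field
#' \eqn{\nabla\mu / \sqrt{|\nabla\mu|^2 + \xi}}, with boundary handling
#' exactly adjoint to the forward differences used by [tv_norm()], so
#' that the pair passes finite-difference gradient checks.
#'
#' @param m an [image_grid()] or plain matrix.
#' @param xi positive smoothing parameter.
#' @return Matrix of the same shape as the image.
#' @export
tv_gradient <- function(m, xi = 1e-15) {
  stopifnot(xi > 0)
  m <- as_values(m)
  d <- tv_diffs(m)
  r <- sqrt(d$dx^2 + d$dy^2 + xi)
  gx <- d$dx / r
  gy <- d$dy / r
  nr <- nrow(m); nc <- ncol(m)
  g <- -(gx + gy)
  g[, 2:nc] <- g[, 2:nc] + gx[, 1:(nc - 1)]
  g[2:nr, ] <- g[2:nr, ] + gy[1:(nr - 1), ]
  g
}

#' Compressed-sensing solver configuration
#'
#' Settings for the joint TV + wavelet-\eqn{\ell_1} + least-squares
#' objective
#' \deqn{J(\mu) = \lambda_1 \|\mu\|_{TV} + \lambda_2 \|\Phi\mu\|_1 + \|A\mu - y\|_2^2}
#' and its nonlinear conjugate gradient solver.  Setting `lambda2 = 0`
#' gives the TV-regularized method as a special case.
#'
#' @param lambda1 TV weight (default 0.001).
#' @param lambda2 wavelet-\eqn{\ell_1} weight (default 0.0005).
#' @param xi smoothing parameter for the absolute values (default 1e-15).
#' @param max_iterations iteration cap (default 150).
#' @param wavelet,levels wavelet family and decomposition depth for
#'   \eqn{\Phi} (default Daubechies-4, 4 levels).
#' @param ls_init,ls_shrink,ls_c1,ls_max_backtracks backtracking line
#'   search: fallback initial step (used when the quadratic model is
#'   degenerate), shrink factor in (0,1), sufficient-decrease constant,
#'   and maximum number of backtracks.
#' @param grad_tol stop when \eqn{\|\nabla J\|_2 < grad\_tol\,(1 + |J|)}.
#' @param x0 optional initial [image_grid()] (default zero image).
#' @return An object of class `cs_config`.
#' @export
cs_config <- function(lambda1 = 1e-3, lambda2 = 5e-4, xi = 1e-15,
                      max_iterations = 150, wavelet = "db4", levels = 4,
                      ls_init = 1.0, ls_shrink = 0.5, ls_c1 = 1e-4,
                      ls_max_backtracks = 20, grad_tol = 1e-6, x0 = NULL) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, xi > 0, max_iterations >= 1,
            ls_shrink > 0, ls_shrink < 1, ls_init > 0, ls_c1 > 0,
            ls_max_backtracks >= 1, grad_tol >= 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, xi = xi,
                 max_iterations = as.integer(max_iterations),
                 wavelet = wavelet, levels = levels,
                 ls_init = ls_init, ls_shrink = ls_shrink, ls_c1 = ls_c1,
                 ls_max_backtracks = as.integer(ls_max_backtracks),
                 grad_tol = grad_tol, x0 = x0),
            class = "cs_config")
}

cs_wavelet_op <- function(cfg, side) {
  if (cfg$lambda2 == 0) NULL else wavelet_operator(side, cfg$wavelet, cfg$levels)
}

#' Reconstruction objective and its gradient
#'
#' `cs_cost` evaluates
#' \eqn{J(\mu) = \lambda_1\|\mu\|_{TV,\xi} + \lambda_2\sum\sqrt{(\Phi\mu)^2+\xi} + \|A\mu-y\|_2^2};
#' `cs_cost_gradient` evaluates
#' \eqn{\nabla J = \lambda_1\nabla\|\mu\|_{TV} + \lambda_2\Phi^T s_\xi(\Phi\mu) + 2A^T(A\mu-y)}
#' where \eqn{s_\xi} is the smoothed sign and \eqn{\Phi^T=\Phi^{-1}} by
#' orthonormality.
#'
#' @param mu an [image_grid()] or matrix iterate.
#' @param A a `system_matrix`.
#' @param y a [sinogram()].
#' @param cfg a [cs_config()].
#' @param wop optional pre-built [wavelet_operator()] to reuse.
#' @return Scalar cost / gradient matrix.
#' @export
cs_cost <- function(mu, A, y, cfg = cs_config(), wop = NULL) {
  m <- as_values(mu)
  r <- as.numeric(A$A %*% flatten_image(m)) - sino_to_vec(y)
  J <- sum(r * r)
  if (cfg$lambda1 > 0) J <- J + cfg$lambda1 * tv_norm(m, cfg$xi)
  if (cfg$lambda2 > 0) {
    if (is.null(wop)) wop <- cs_wavelet_op(cfg, nrow(m))
    J <- J + cfg$lambda2 * sum(smoothed_abs(wavelet_forward(wop, m), cfg$xi))
  }
  J
}

#' @rdname cs_cost
#' @export
cs_cost_gradient <- function(mu, A, y, cfg = cs_config(), wop = NULL) {
  m <- as_values(mu)
  r <- as.numeric(A$A %*% flatten_image(m)) - sino_to_vec(y)
  g <- 2 * unflatten_image(as.numeric(Matrix::crossprod(A$A, r)), nrow(m))
  if (cfg$lambda1 > 0) g <- g + cfg$lambda1 * tv_gradient(m, cfg$xi)
  if (cfg$lambda2 > 0) {
    if (is.null(wop)) wop <- cs_wavelet_op(cfg, nrow(m))
    w <- wavelet_forward(wop, m)
    g <- g + cfg$lambda2 * wavelet_inverse(wop, smoothed_abs_grad(w, cfg$xi))
  }
  g
}

# Regularizer part of the cost only (the data term is handled
# incrementally in the line search via r(alpha) = r0 + alpha * A d).
cs_reg_cost <- function(m, cfg, wop) {
  J <- 0
  if (cfg$lambda1 > 0) J <- J + cfg$lambda1 * tv_norm(m, cfg$xi)
  if (cfg$lambda2 > 0)
    J <- J + cfg$lambda2 * sum(smoothed_abs(wavelet_forward(wop, m), cfg$xi))
  J
}

#' Nonlinear conjugate gradient reconstruction
#'
#' Minimizes the joint TV + wavelet-\eqn{\ell_1} + least-squares
#' objective by Polak-Ribiere+ nonlinear conjugate gradient with an
#' Armijo backtracking line search; the search direction is reset to
#' steepest descent whenever it fails to be a descent direction.  The
#' line search starts from the exact minimizer of the (dominant)
#' quadratic data term along the search direction,
#' \eqn{\alpha_0 = -g^T d / (2\|Ad\|_2^2)}, and backtracks from there;
#' only steps that strictly decrease the objective are accepted, so the
#' recorded cost trace is nonincreasing by construction.  The TV-only
#' method is the `lambda2 = 0` special case ([tv_reconstruct()]).
#'
#' @param A a `system_matrix`.
#' @param y a [sinogram()].
#' @param cfg a [cs_config()].
#' @return A [recon_result()]; `trace` holds the objective value at the
#'   initial point and after each accepted iteration.
#' @export
nlcg_reconstruct <- function(A, y, cfg = cs_config()) {
  stopifnot(inherits(A, "system_matrix"), inherits(y, "sinogram"))
  side <- A$side_px
  yv <- sino_to_vec(y)
  if (length(yv) != nrow(A$A)) stop("sinogram shape does not match the system matrix")
  wop <- cs_wavelet_op(cfg, side)
  x <- if (is.null(cfg$x0)) matrix(0, side, side) else as_values(cfg$x0)

  M <- A$A
  r <- as.numeric(M %*% flatten_image(x)) - yv
  J <- sum(r * r) + cs_reg_cost(x, cfg, wop)
  trace <- J
  grad <- function(xm, rv) {
    g <- 2 * unflatten_image(as.numeric(Matrix::crossprod(M, rv)), side)
    if (cfg$lambda1 > 0) g <- g + cfg$lambda1 * tv_gradient(xm, cfg$xi)
    if (cfg$lambda2 > 0)
      g <- g + cfg$lambda2 *
        wavelet_inverse(wop, smoothed_abs_grad(wavelet_forward(wop, xm), cfg$xi))
    g
  }
  g <- grad(x, r)
  converged <- FALSE
  it_done <- 0L
  if (sqrt(sum(g * g)) < cfg$grad_tol * (1 + abs(J))) {
    return(recon_result(image_grid(x, A$pixel_size), trace,
                        if (cfg$lambda2 == 0) "tv" else "cs", 0L, TRUE))
  }
  d <- -g

  for (it in seq_len(cfg$max_iterations)) {
    gd <- sum(g * d)
    if (gd >= 0) { d <- -g; gd <- sum(g * d) }   # restart on non-descent
    Ad <- as.numeric(M %*% flatten_image(d))
    # quadratic-model initial step: exact for the data term along d
    denom <- 2 * sum(Ad * Ad)
    alpha <- if (denom > 0) -gd / denom else cfg$ls_init
    accepted <- FALSE
    for (bt in seq_len(cfg$ls_max_backtracks)) {
      xn <- x + alpha * d
      rn <- r + alpha * Ad
      Jn <- sum(rn * rn) + cs_reg_cost(xn, cfg, wop)
      if (is.finite(Jn) && Jn <= J + cfg$ls_c1 * alpha * gd && Jn < J) {
        accepted <- TRUE
        break
      }
      alpha <- alpha * cfg$ls_shrink
    }
    if (!accepted) {
      if (!isTRUE(all.equal(d, -g))) {
        # retry once along steepest descent before giving up
        d <- -g
        next
      }
      converged <- TRUE
      break
    }
    x <- xn; r <- rn
    gn <- grad(x, r)
    beta <- max(0, sum(gn * (gn - g)) / sum(g * g))   # Polak-Ribiere+
    d <- -gn + beta * d
    g <- gn
    J <- Jn
    trace <- c(trace, J)
    it_done <- it
    if (sqrt(sum(g * g)) < cfg$grad_tol * (1 + abs(J))) {
      converged <- TRUE
      break
    }
  }
  recon_result(image_grid(x, A$pixel_size), trace,
               if (cfg$lambda2 == 0) "tv" else "cs", it_done, converged)
}

#' TV-regularized reconstruction
#'
#' Convenience wrapper: the joint solver with the wavelet weight set to
#' zero, minimizing \eqn{\lambda\|\mu\|_{TV} + \|A\mu - y\|_2^2}.
#'
#' @inheritParams nlcg_reconstruct
#' @param lambda TV regularization weight (default 0.0005).
#' @param ... further arguments passed to [cs_config()].
#' @export
tv_reconstruct <- function(A, y, lambda = 5e-4, ...) {
  nlcg_reconstruct(A, y, cs_config(lambda1 = lambda, lambda2 = 0, ...))
}

#' Regularization parameter search
#'
#' Reproduces the grid/alternating search used to pick regularization
#' weights.  For the TV method a single grid over \eqn{\lambda} is
#' scanned; for the joint method the two weights are optimized by
#' alternating one-dimensional grid searches (fix \eqn{\lambda_2},
#' scan \eqn{\lambda_1}; fix the winner, scan \eqn{\lambda_2}; repeat)
#' until neither coordinate changes.  Reconstruction error is the RRMSE
#' against the supplied reference image.
#'
#' @param A a `system_matrix`.
#' @param y the (typically decimated) training [sinogram()].
#' @param reference reference [image_grid()] (e.g. a full-view FBP
#'   reconstruction, or the ground truth in simulations).
#' @param method `"tv"` or `"joint"`.
#' @param lambda_grid candidate \eqn{\lambda} values (TV method).
#' @param lambda1_grid,lambda2_grid candidate weights (joint method).
#' @param lambda2_init starting \eqn{\lambda_2} for the alternating
#'   search (default 0.0005).
#' @param config base [cs_config()] supplying solver settings.
#' @param max_cycles cap on alternating cycles.
#' @return A list with the selected weights and a data frame `surface`
#'   of every evaluated candidate and its RRMSE.
#' @export
param_search <- function(A, y, reference, method = c("tv", "joint"),
                         lambda_grid = NULL, lambda1_grid = NULL,
                         lambda2_grid = NULL, lambda2_init = 5e-4,
                         config = cs_config(), max_cycles = 5) {
  method <- match.arg(method)
  evals <- list()
  err_for <- function(l1, l2) {
    key <- paste(format(l1, digits = 17), format(l2, digits = 17))
    if (!is.null(evals[[key]])) return(evals[[key]])
    cfg <- config
    cfg$lambda1 <- l1
    cfg$lambda2 <- l2
    rec <- nlcg_reconstruct(A, y, cfg)
    e <- rrmse(rec$image, reference)
    evals[[key]] <<- e
    e
  }
  if (method == "tv") {
    if (is.null(lambda_grid) || length(lambda_grid) == 0)
      stop("lambda_grid must be non-empty")
    errs <- vapply(lambda_grid, err_for, numeric(1), l2 = 0)
    best <- which.min(errs)
    return(list(lambda = lambda_grid[best],
                surface = data.frame(lambda = lambda_grid, rrmse = errs)))
  }
  if (is.null(lambda1_grid) || is.null(lambda2_grid) ||
      length(lambda1_grid) == 0 || length(lambda2_grid) == 0)
    stop("lambda1_grid and lambda2_grid must be non-empty")
  l2 <- lambda2_init
  l1 <- NA_real_
  for (cycle in seq_len(max_cycles)) {
    e1 <- vapply(lambda1_grid, err_for, numeric(1), l2 = l2)
    l1_new <- lambda1_grid[which.min(e1)]
    e2 <- vapply(lambda2_grid, function(l) err_for(l1_new, l), numeric(1))
    l2_new <- lambda2_grid[which.min(e2)]
    if (isTRUE(l1_new == l1) && isTRUE(l2_new == l2)) break
    l1 <- l1_new
    l2 <- l2_new
  }
  keys <- do.call(rbind, strsplit(names(evals), " "))
  list(lambda1 = l1, lambda2 = l2,
       surface = data.frame(lambda1 = as.numeric(keys[, 1]),
                            lambda2 = as.numeric(keys[, 2]),
                            rrmse = unlist(evals, use.names = FALSE)))
}
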