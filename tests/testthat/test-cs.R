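test_that("smoothed absolute value and its derivative behave", {
  expect_equal(smoothed_abs(0, 1e-15), sqrt(1e-15))
  expect_equal(smoothed_abs_grad(0, 1e-15), 0)
  expect_equal(smoothed_abs(3, 1e-15), 3, tolerance = 1e-12)
  # derivative matches central differences
  h <- 1e-6
  num <- (smoothed_abs(1 + h) - smoothed_abs(1 - h)) / (2 * h)
  expect_equal(smoothed_abs_grad(1), num, tolerance = 1e-6)
  expect_equal(smoothed_abs(c(-2, 0, 2)), c(2, sqrt(1e-15), 2),
               tolerance = 1e-12)
})

test_that("TV norm follows the forward-difference convention", {
  expect_equal(tv_norm(matrix(5, 7, 7)), 0)
  # two unit horizontal jumps, no vertical ones
  expect_equal(tv_norm(matrix(c(0, 0, 1, 1), 2, 2)), 2)
  set.seed(2)
  m <- matrix(rnorm(36), 6, 6)
  expect_equal(tv_norm(m), tv_norm(t(m)), tolerance = 1e-12)
})

test_that("TV gradient is adjoint-consistent with the TV norm", {
  expect_true(all(tv_gradient(matrix(3, 5, 5)) == 0))
  set.seed(4)
  m <- matrix(rnorm(256), 16, 16)
  xi <- 1e-6   # keep the FD check well-conditioned
  g <- tv_gradient(m, xi)
  num <- numerical_gradient(function(x) tv_norm(x, xi), m)
  expect_lt(max(abs(g - num)) / max(abs(num)), 1e-4)
  # shift invariance implies a zero-mean gradient
  expect_equal(sum(tv_gradient(m, 1e-15)), 0, tolerance = 1e-8)
})

test_that("wavelet operator is orthonormal with perfect reconstruction", {
  # hand Haar example: constant 2x2 image of value a
  op <- wavelet_operator(2, "haar", 1)
  W <- wavelet_forward(op, matrix(3, 2, 2))
  expect_equal(W[1, 1], 6)          # approximation = 2a
  expect_equal(sum(abs(W[-1])), 0, tolerance = 1e-12)

  for (family in c("haar", "db4")) {
    for (side in c(16, 32)) {
      op <- wavelet_operator(side, family, 4)
      set.seed(side)
      m <- matrix(rnorm(side^2), side, side)
      w <- wavelet_forward(op, m)
      expect_equal(sqrt(sum(w^2)), sqrt(sum(m^2)), tolerance = 1e-10)
      expect_equal(wavelet_inverse(op, w), m, tolerance = 1e-10)
    }
  }
  # non-power-of-two sides are padded internally
  op12 <- wavelet_operator(12, "db4", 3)
  m12 <- matrix(rnorm(144), 12, 12)
  expect_equal(dim(wavelet_forward(op12, m12)), c(16, 16))
  expect_equal(wavelet_inverse(op12, wavelet_forward(op12, m12)), m12,
               tolerance = 1e-10)
})

test_that("cost decomposes into its three terms", {
  set.seed(9)
  ph <- random_grid(16, 9)
  geom <- uniform_geometry(10, 16)
  A <- build_system_matrix(ph, geom)
  y <- forward_project(A, disc_phantom(16, 0.3))

  # lambda1 = lambda2 = 0 reduces to plain least squares
  cfg0 <- cs_config(lambda1 = 0, lambda2 = 0)
  r <- as.numeric(A$A %*% as.vector(t(ph$values))) - as.vector(t(y$values))
  expect_equal(cs_cost(ph, A, y, cfg0), sum(r^2), tolerance = 1e-12)

  # zero image against zero data: forced value from the smoothed zeros
  y0 <- sinogram(matrix(0, 10, 16), geom)
  z <- image_grid(matrix(0, 16, 16))
  cfg <- cs_config(lambda1 = 2, lambda2 = 3, xi = 1e-15)
  P <- 16^2
  Q <- wavelet_operator(16, cfg$wavelet, cfg$levels)$n_coeffs
  expect_equal(cs_cost(z, A, y0, cfg), (2 * P + 3 * Q) * sqrt(1e-15),
               tolerance = 1e-9)

  # term-by-term oracle on a random instance
  cfgr <- cs_config(lambda1 = 0.3, lambda2 = 0.7, xi = 1e-8)
  op <- wavelet_operator(16, cfgr$wavelet, cfgr$levels)
  expected <- 0.3 * tv_norm(ph$values, 1e-8) +
    0.7 * sum(sqrt(wavelet_forward(op, ph$values)^2 + 1e-8)) + sum(r^2)
  expect_equal(cs_cost(ph, A, y, cfgr), expected, tolerance = 1e-10)
})

test_that("cost gradient matches finite differences for all weight combos", {
  set.seed(14)
  side <- 16
  ph <- random_grid(side, 14)
  geom <- uniform_geometry(10, side)
  A <- build_system_matrix(ph, geom)
  y <- forward_project(A, disc_phantom(side, 0.3))
  for (l1 in c(0, 1e-3)) {
    for (l2 in c(0, 1e-3)) {
      cfg <- cs_config(lambda1 = l1, lambda2 = l2, xi = 1e-15)
      g <- cs_cost_gradient(ph, A, y, cfg)
      num <- numerical_gradient(function(m) cs_cost(m, A, y, cfg), ph$values)
      expect_lt(max(abs(g - num)) / max(abs(num)), 1e-4)
    }
  }
  # data-term gradient equals the dense-matrix expression
  cfg0 <- cs_config(lambda1 = 0, lambda2 = 0)
  D <- as.matrix(A$A)
  mu <- as.vector(t(ph$values))
  dense <- 2 * t(D) %*% (D %*% mu - as.vector(t(y$values)))
  expect_equal(as.vector(t(cs_cost_gradient(ph, A, y, cfg0))),
               as.numeric(dense), tolerance = 1e-10)
  # zero residual, no regularization: zero gradient
  yfit <- forward_project(A, ph)
  expect_equal(max(abs(cs_cost_gradient(ph, A, yfit, cfg0))), 0,
               tolerance = 1e-10)
})

test_that("NLCG solves an invertible system and respects stationarity", {
  # square well-posed system: dense angles on a tiny grid
  side <- 8
  ph <- disc_phantom(side, 0.3)
  geom <- uniform_geometry(16, side)   # 128 rays vs 64 unknowns
  A <- build_system_matrix(ph, geom)
  y <- forward_project(A, ph)
  cfg <- cs_config(lambda1 = 0, lambda2 = 0, max_iterations = 300,
                   grad_tol = 1e-10)
  res <- nlcg_reconstruct(A, y, cfg)
  fit <- as.numeric(A$A %*% as.vector(t(res$image$values)))
  expect_lt(sqrt(sum((fit - as.vector(t(y$values)))^2)) /
              sqrt(sum(y$values^2)), 1e-6)
  # compare against the direct least-squares oracle
  D <- as.matrix(A$A)
  xstar <- qr.solve(crossprod(D), crossprod(D, as.vector(t(y$values))))
  expect_lt(sqrt(sum((as.vector(t(res$image$values)) - xstar)^2)) /
              sqrt(sum(xstar^2)), 1e-4)

  # starting at the minimizer returns it unchanged
  cfg2 <- cs_config(lambda1 = 0, lambda2 = 0, x0 = ph)
  res2 <- nlcg_reconstruct(A, y, cfg2)
  expect_identical(res2$image$values, ph$values)
  expect_true(res2$converged)

  # cost trace is nonincreasing on regularized runs
  y2 <- decimate_views(y, 5)
  A2 <- build_system_matrix(ph, y2$geometry)
  res3 <- nlcg_reconstruct(A2, y2, cs_config(max_iterations = 40))
  expect_true(all(diff(res3$trace) <= 0))
})

test_that("TV-only solve is independent of the wavelet configuration", {
  ph <- disc_phantom(16, 0.3)
  y <- simulate_sinogram(ph, uniform_geometry(8, 16))
  A <- build_system_matrix(ph, y$geometry)
  ra <- nlcg_reconstruct(A, y, cs_config(lambda1 = 1e-3, lambda2 = 0,
                                         wavelet = "db4", max_iterations = 30))
  rb <- nlcg_reconstruct(A, y, cs_config(lambda1 = 1e-3, lambda2 = 0,
                                         wavelet = "haar", levels = 1,
                                         max_iterations = 30))
  expect_identical(ra$image$values, rb$image$values)
})

test_that("parameter search returns exhaustive-search optima", {
  ph <- disc_phantom(16, 0.3)
  y <- simulate_sinogram(ph, uniform_geometry(10, 16))
  A <- build_system_matrix(ph, y$geometry)
  base <- cs_config(max_iterations = 25)
  # single candidate: returned as-is
  single <- param_search(A, y, ph, "tv", lambda_grid = 0.01, config = base)
  expect_equal(single$lambda, 0.01)
  # grid search result equals the argmin of its own error surface
  grid <- c(1e-4, 1e-3, 1e-2, 1e-1, 1)
  ps <- param_search(A, y, ph, "tv", lambda_grid = grid, config = base)
  expect_equal(ps$lambda, ps$surface$lambda[which.min(ps$surface$rrmse)])
  # exhaustive oracle: recompute every candidate independently
  errs <- sapply(grid, function(l) {
    rrmse(nlcg_reconstruct(A, y, cs_config(lambda1 = l, lambda2 = 0,
                                           max_iterations = 25))$image, ph)
  })
  expect_equal(ps$lambda, grid[which.min(errs)])
  expect_equal(sort(ps$surface$rrmse), sort(errs), tolerance = 1e-12)
  # joint alternating search lands on a coordinate-wise minimum
  psj <- param_search(A, y, ph, "joint", lambda1_grid = c(1e-3, 1e-2),
                      lambda2_grid = c(1e-4, 1e-3), config = base,
                      max_cycles = 3)
  expect_true(psj$lambda1 %in% c(1e-3, 1e-2))
  expect_true(psj$lambda2 %in% c(1e-4, 1e-3))
  expect_error(param_search(A, y, ph, "tv", lambda_grid = numeric(0)),
               "non-empty")
})

test_that("shrinking xi perturbs the objective by at most the stated bound", {
  ph <- disc_phantom(16, 0.3)
  y <- simulate_sinogram(ph, uniform_geometry(8, 16))
  A <- build_system_matrix(ph, y$geometry)
  P <- 16^2
  cfg_a <- cs_config(lambda1 = 1e-3, lambda2 = 1e-3, xi = 1e-15)
  cfg_b <- cs_config(lambda1 = 1e-3, lambda2 = 1e-3, xi = 1e-20)
  Q <- wavelet_operator(16, cfg_a$wavelet, cfg_a$levels)$n_coeffs
  bound <- (1e-3 * P + 1e-3 * Q) * sqrt(1e-15)
  expect_lt(abs(cs_cost(ph, A, y, cfg_a) - cs_cost(ph, A, y, cfg_b)), bound)
})
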