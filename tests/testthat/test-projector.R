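test_that("system matrix reproduces hand-checkable ray geometries", {
  # single unit pixel, axis-aligned ray through its centre
  A1 <- build_system_matrix(image_grid(matrix(1, 1, 1)),
                            projection_geometry(0, 1, 1))
  expect_equal(as.matrix(A1$A), matrix(1, 1, 1), tolerance = 1e-12)

  # 2x2 grid, horizontal rays (beam along x): detector offsets -0.5, 0.5
  # hit the bottom and top rows, crossing two unit pixels each
  A2 <- build_system_matrix(image_grid(matrix(0, 2, 2)),
                            projection_geometry(90, 2, 1))
  M <- as.matrix(A2$A)
  expect_equal(M[2, ], c(1, 1, 0, 0))  # t = +0.5: top row (pixels 1, 2)
  expect_equal(M[1, ], c(0, 0, 1, 1))  # t = -0.5: bottom row

  # 45-degree ray through the centre crosses the grid diagonal:
  # total length 2*sqrt(2) split between two pixels
  A3 <- build_system_matrix(image_grid(matrix(0, 2, 2)),
                            projection_geometry(45, 1, 1))
  v <- sort(as.numeric(as.matrix(A3$A)[1, as.matrix(A3$A)[1, ] > 0]))
  expect_equal(v, c(sqrt(2), sqrt(2)), tolerance = 1e-12)
})

test_that("sparse matrix agrees with the dense clipping oracle", {
  for (side in c(4, 8, 16)) {
    angles <- c(0, 17.3, 45, 90, 121.7, 160)
    # even detector count: no ray sits exactly on a pixel boundary, where
    # the per-pixel clipping oracle would count the chord twice
    n_det <- side + 2
    grid <- image_grid(matrix(0, side, side), pixel_size = 0.7)
    A <- build_system_matrix(grid,
                             projection_geometry(angles, n_det, 0.5))
    D <- dense_system_oracle(side, 0.7, angles, n_det, 0.5)
    expect_equal(as.matrix(A$A), D, tolerance = 1e-9,
                 ignore_attr = TRUE)
    # no chord exceeds the pixel diagonal
    expect_lte(max(A$A@x), sqrt(2) * 0.7 + 1e-12)
    expect_gte(min(A$A@x), 0)
  }
})

test_that("row sums match the chord of the ray through the image square", {
  side <- 8
  grid <- image_grid(matrix(0, side, side))
  angles <- c(0, 30, 75.5, 120)
  geom <- projection_geometry(angles, 12, 0.9)
  A <- build_system_matrix(grid, geom)
  h <- side / 2
  for (v in seq_along(angles)) {
    th <- angles[v] * pi / 180
    for (k in 1:12) {
      t <- ((k - 1) - 11 / 2) * 0.9
      chord <- chord_in_box(c(t * cos(th), t * sin(th)),
                            c(-sin(th), cos(th)), c(-h, h), c(-h, h))
      expect_equal(A$row_sums[(v - 1) * 12 + k], chord, tolerance = 1e-9)
    }
  }
})

test_that("forward projection is linear and matches analytic chords", {
  grid <- disc_phantom(32, radius_frac = 0.25)
  geom <- projection_geometry(c(0, 90), 33, 1)
  A <- build_system_matrix(grid, geom)

  zero <- forward_project(A, image_grid(matrix(0, 32, 32)))
  expect_true(all(zero$values == 0))

  y1 <- forward_project(A, grid)
  y3 <- forward_project(A, image_grid(3 * grid$values))
  expect_equal(y3$values, 3 * y1$values, tolerance = 1e-12)

  # ray through the centre of a unit disc of radius r: integral ~ 2r
  r <- 0.25 * 32
  expect_equal(y1$values[1, 17], 2 * r, tolerance = 2)  # 2 * pixel_size
})

test_that("back projection is the exact adjoint", {
  set.seed(42)
  grid <- image_grid(matrix(0, 8, 8))
  geom <- uniform_geometry(10, 8)
  A <- build_system_matrix(grid, geom)
  for (rep in 1:5) {
    mu <- image_grid(matrix(rnorm(64), 8, 8))
    yv <- matrix(rnorm(80), 10, 8)
    lhs <- sum(forward_project(A, mu)$values * yv)
    bp <- back_project(A, sinogram(yv, geom))
    rhs <- sum(mu$values * bp$values)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  # zero sinogram maps to zero image
  expect_true(all(back_project(A, sinogram(matrix(0, 10, 8), geom))$values == 0))
  # unit impulse at ray j extracts row j of A
  j <- 23
  ev <- numeric(80); ev[j] <- 1
  imp <- back_project(A, sinogram(matrix(ev, 10, 8, byrow = TRUE), geom))
  expect_equal(as.vector(t(imp$values)), as.numeric(as.matrix(A$A)[j, ]),
               tolerance = 1e-12)
})

test_that("rotating the image by 90 degrees permutes per-view projections", {
  set.seed(3)
  m <- matrix(rnorm(144), 12, 12)
  grid <- image_grid(m)
  # counter-clockwise rotation by 90 degrees
  grid_rot <- image_grid(t(m)[nrow(m):1, ])
  angles <- c(0, 30, 60, 90, 120, 150)
  geom <- projection_geometry(angles, 12, 1)
  y <- forward_project(build_system_matrix(grid, geom), grid)
  y_rot <- forward_project(build_system_matrix(grid_rot, geom), grid_rot)
  # view at angle a of the rotated image equals (up to detector flip)
  # the view at (a + 90) mod 180 of the original
  for (v in seq_along(angles)) {
    target <- (angles[v] + 90) %% 180
    w <- which(abs(angles - target) < 1e-9)
    expect_equal(sort(y_rot$values[v, ]), sort(y$values[w, ]),
                 tolerance = 1e-9)
  }
})

test_that("invalid geometry and shape mismatches are rejected", {
  expect_error(projection_geometry(numeric(0), 4), "at least one")
  expect_error(projection_geometry(c(0, 181), 4), "180")
  expect_error(projection_geometry(c(10, 5), 4), "increasing")
  expect_error(image_grid(matrix(0, 2, 3)), "square")
  expect_error(image_grid(matrix(0, 2, 2), pixel_size = 0), "positive")
  g <- image_grid(matrix(0, 4, 4))
  A <- build_system_matrix(g, uniform_geometry(3, 4))
  expect_error(forward_project(A, image_grid(matrix(0, 5, 5))), "side")
  expect_error(back_project(A, sinogram(matrix(0, 3, 5),
                                        uniform_geometry(3, 5))), "match")
})
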