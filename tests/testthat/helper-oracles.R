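# Independent oracles used across the test files.  These deliberately
# share no code with the package internals.

# Chord length of the segment of a ray inside an axis-aligned box,
# by slab (Liang-Barsky) clipping.  Ray: point p0, unit direction d.
chord_in_box <- function(p0, d, xlim, ylim) {
  tmin <- -Inf; tmax <- Inf
  for (ax in 1:2) {
    lim <- if (ax == 1) xlim else ylim
    if (abs(d[ax]) > 1e-14) {
      a <- (lim[1] - p0[ax]) / d[ax]
      b <- (lim[2] - p0[ax]) / d[ax]
      tmin <- max(tmin, min(a, b))
      tmax <- min(tmax, max(a, b))
    } else if (p0[ax] < lim[1] || p0[ax] > lim[2]) {
      return(0)
    }
  }
  max(0, tmax - tmin)
}

# Dense system matrix built purely from the clipping oracle, using the
# package's documented conventions (centred grid, row-major pixels,
# ray (theta, t) through (t cos, t sin) with direction (-sin, cos)).
dense_system_oracle <- function(side, pixel_size, angles_deg, n_det, spacing) {
  h <- side * pixel_size / 2
  m <- length(angles_deg) * n_det
  A <- matrix(0, m, side^2)
  for (v in seq_along(angles_deg)) {
    th <- angles_deg[v] * pi / 180
    d <- c(-sin(th), cos(th))
    for (k in seq_len(n_det)) {
      t <- ((k - 1) - (n_det - 1) / 2) * spacing
      p0 <- c(t * cos(th), t * sin(th))
      ray <- (v - 1) * n_det + k
      for (r in seq_len(side)) {
        ylim <- c(h - r * pixel_size, h - (r - 1) * pixel_size)
        for (cc in seq_len(side)) {
          xlim <- c(-h + (cc - 1) * pixel_size, -h + cc * pixel_size)
          len <- chord_in_box(p0, d, xlim, ylim)
          if (len > 0) A[ray, (r - 1) * side + cc] <- len
        }
      }
    }
  }
  A
}

# Central finite differences of a scalar function of a matrix argument.
numerical_gradient <- function(f, m, h = 1e-6) {
  g <- m * 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      mp <- m; mp[i, j] <- mp[i, j] + h
      mm <- m; mm[i, j] <- mm[i, j] - h
      g[i, j] <- (f(mp) - f(mm)) / (2 * h)
    }
  }
  g
}

# Direct window-by-window SSIM evaluation (weighted local moments,
# three-factor luminance/contrast/structure product, mean pooling).
ssim_brute <- function(a, b, win = 11, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                       L = diff(range(b))) {
  if (L <= 0) L <- 1
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2; C3 <- C2 / 2
  k <- seq_len(win) - (win + 1) / 2
  w1 <- exp(-k^2 / (2 * sigma^2)); w1 <- w1 / sum(w1)
  W <- outer(w1, w1)
  n <- nrow(a) - win + 1
  vals <- numeric(0)
  for (i in seq_len(n)) {
    for (j in seq_len(ncol(a) - win + 1)) {
      pa <- a[i:(i + win - 1), j:(j + win - 1)]
      pb <- b[i:(i + win - 1), j:(j + win - 1)]
      mu_a <- sum(W * pa); mu_b <- sum(W * pb)
      va <- max(sum(W * pa^2) - mu_a^2, 0)
      vb <- max(sum(W * pb^2) - mu_b^2, 0)
      cab <- sum(W * pa * pb) - mu_a * mu_b
      l <- (2 * mu_a * mu_b + C1) / (mu_a^2 + mu_b^2 + C1)
      co <- (2 * sqrt(va) * sqrt(vb) + C2) / (va + vb + C2)
      st <- (cab + C3) / (sqrt(va) * sqrt(vb) + C3)
      vals <- c(vals, l * co * st)
    }
  }
  mean(vals)
}

# Small reusable fixtures
disc_phantom <- function(side, radius_frac = 0.3, value = 1) {
  generate_phantom(phantom_spec(side, list(
    list(shape = "disc", center = c(0, 0), radius = radius_frac * side,
         value = value))))
}

random_grid <- function(side, seed) {
  set.seed(seed)
  image_grid(matrix(rnorm(side^2), side, side))
}
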