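# Brute-force oracles and fixture builders shared across the test files.
# Oracles deliberately re-derive each quantity by the most direct route
# available (exhaustive scans, naive envelopes, Monte-Carlo counting) so the
# fast implementation is checked against an independent computation.

rand_points <- function(n, domain = c(0, 1, 0, 1)) {
  tibble::tibble(
    x = runif(n, domain[1], domain[2]),
    y = runif(n, domain[3], domain[4])
  )
}

# rectangular raster map whose spectra are affine in (x, y): every channel
# f_j(x, y) = a_j x + b_j y + c_j, so any linear interpolation reproduces it
make_affine_map <- function(n_row = 6, n_col = 7, n_f = 5, step = 1) {
  pos <- expand.grid(
    x = (seq_len(n_col) - 0.5) * step,
    y = (seq_len(n_row) - 0.5) * step
  )
  a <- seq_len(n_f)
  b <- rev(seq_len(n_f)) / 2
  c0 <- seq_len(n_f) / 3
  spectra <- outer(pos$x, a) + outer(pos$y, b) +
    matrix(c0, nrow(pos), n_f, byrow = TRUE)
  spectral_map(pos, spectra, axis = seq(1000, by = 10, length.out = n_f))
}

# constant-spectrum raster map
make_constant_map <- function(n_row = 5, n_col = 5, n_f = 4, value = 1) {
  pos <- expand.grid(x = seq_len(n_col), y = seq_len(n_row))
  spectral_map(pos, matrix(value, nrow(pos), n_f),
               axis = seq(1000, by = 10, length.out = n_f))
}

# independent second implementation of the leave-one-out rebuild loop,
# driven through the public build/predict surface with the documented
# nearest-support fallback on degenerate reduced support
oracle_loo <- function(points, values) {
  values <- as.matrix(values)
  n <- nrow(points)
  dom <- c(min(points$x) - 1, max(points$x) + 1,
           min(points$y) - 1, max(points$y) + 1)
  vapply(seq_len(n), function(i) {
    sub <- points[-i, , drop = FALSE]
    subv <- values[-i, , drop = FALSE]
    pred <- tryCatch({
      m <- build_model(sub, subv, domain = dom)
      predict(m, points[i, c("x", "y")])
    }, error = function(e) {
      j <- which.min((sub$x - points$x[i])^2 + (sub$y - points$y[i])^2)
      subv[j, , drop = FALSE]
    })
    sqrt(sum((values[i, ] - pred)^2))
  }, numeric(1))
}

# naive O(n^2) lower convex envelope: from each hull vertex take the
# minimum-slope segment to any point to its right
oracle_lower_envelope <- function(x, y) {
  n <- length(x)
  hull <- 1L
  i <- 1L
  while (i < n) {
    sl <- (y[(i + 1):n] - y[i]) / (x[(i + 1):n] - x[i])
    j <- i + which.min(sl)
    hull <- c(hull, j)
    i <- j
  }
  approx(x[hull], y[hull], xout = x)$y
}

# Monte-Carlo style Voronoi areas by nearest-owner counting on a probe grid
mc_voronoi_areas <- function(points, domain, n_grid = 500) {
  gx <- domain[1] + (seq_len(n_grid) - 0.5) * (domain[2] - domain[1]) / n_grid
  gy <- domain[3] + (seq_len(n_grid) - 0.5) * (domain[4] - domain[3]) / n_grid
  qx <- rep(gx, times = n_grid)
  qy <- rep(gy, each = n_grid)
  best <- rep(1L, length(qx))
  bestd <- (qx - points$x[1])^2 + (qy - points$y[1])^2
  for (i in seq_len(nrow(points))[-1]) {
    d <- (qx - points$x[i])^2 + (qy - points$y[i])^2
    upd <- d < bestd
    best[upd] <- i
    bestd[upd] <- d[upd]
  }
  tabulate(best, nbins = nrow(points)) *
    (domain[2] - domain[1]) * (domain[4] - domain[3]) / n_grid^2
}

# which query points lie inside the convex hull of `pts`
points_in_hull <- function(pts, q, tol = 1e-12) {
  h <- chull(pts$x, pts$y)
  hx <- pts$x[h]
  hy <- pts$y[h]
  n <- length(h)
  inside <- rep(TRUE, nrow(q))
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    cr <- (hx[k2] - hx[k]) * (q$y - hy[k]) - (hy[k2] - hy[k]) * (q$x - hx[k])
    inside <- inside & (cr <= tol)  # chull returns clockwise order
  }
  inside
}

# exhaustive nearest-point scan (lowest index on ties)
brute_nearest <- function(px, py, qx, qy) {
  vapply(seq_along(qx), function(q) {
    which.min((px - qx[q])^2 + (py - qy[q])^2)
  }, integer(1))
}

# independent per-triangle barycentric evaluation over a given triangulation
oracle_bary_eval <- function(points, values, queries) {
  values <- as.matrix(values)
  tri <- livsampler:::cpp_triangulate(points$x, points$y)
  out <- matrix(NA_real_, nrow(queries), ncol(values))
  for (q in seq_len(nrow(queries))) {
    qx <- queries$x[q]
    qy <- queries$y[q]
    for (t in seq_len(nrow(tri))) {
      i <- tri[t, ]
      A <- rbind(cbind(points$x[i], points$y[i], 1))
      w <- tryCatch(solve(t(A), c(qx, qy, 1)), error = function(e) NULL)
      if (!is.null(w) && all(w >= -1e-9)) {
        out[q, ] <- colSums(w * values[i, , drop = FALSE])
        break
      }
    }
    if (anyNA(out[q, ])) {  # outside hull: nearest support
      j <- brute_nearest(points$x, points$y, qx, qy)
      out[q, ] <- values[j, , drop = FALSE]
    }
  }
  out
}
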