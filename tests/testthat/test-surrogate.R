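test_that("the surrogate reproduces planes, support values, and the barycentric oracle", {
  set.seed(7)
  dom <- c(0, 1, 0, 1)
  pts <- rand_points(6)
  vals <- cbind(2 * pts$x - pts$y + 3)
  m <- build_model(pts, vals, dom)
  q <- tibble::tibble(x = runif(40, 0.3, 0.7), y = runif(40, 0.3, 0.7))
  inside <- q[points_in_hull(pts, q), , drop = FALSE]
  expect_gt(nrow(inside), 0)
  pred <- predict(m, inside)
  expect_lt(max(abs(pred - (2 * inside$x - inside$y + 3))), 1e-9)

  # interpolation identity at the support
  expect_identical(unname(predict(m, pts)), unname(vals))

  # random configuration against the independent per-triangle oracle
  pts2 <- rand_points(10)
  vals2 <- matrix(rnorm(30), 10, 3)
  m2 <- build_model(pts2, vals2, dom)
  q2 <- rand_points(60)
  expect_equal(unname(predict(m2, q2)), oracle_bary_eval(pts2, vals2, q2),
               tolerance = 1e-9)

  # constant supports give a constant field everywhere, including outside hull
  m3 <- build_model(pts2, rep(4.5, 10), dom)
  expect_equal(as.vector(predict(m3, rand_points(25))), rep(4.5, 25))

  # outside-hull queries fall back to the nearest support value
  cl <- tibble::tibble(x = runif(8, 0.4, 0.6), y = runif(8, 0.4, 0.6))
  vcl <- matrix(rnorm(16), 8, 2)
  mcl <- build_model(cl, vcl, dom)
  corners <- tibble::tibble(x = c(0.01, 0.99, 0.01, 0.99),
                            y = c(0.01, 0.02, 0.98, 0.99))
  nn <- brute_nearest(cl$x, cl$y, corners$x, corners$y)
  expect_identical(unname(predict(mcl, corners)), unname(vcl[nn, ]))

  expect_error(build_model(pts[1:2, ], vals[1:2, ], dom), "degenerate support")
  coll <- tibble::tibble(x = c(0.1, 0.2, 0.3, 0.4), y = c(0.1, 0.2, 0.3, 0.4))
  expect_error(build_model(coll, 1:4, dom), "degenerate support")
  expect_error(build_model(pts[c(1, 1, 2, 3), ], 1:4, dom), "duplicate point")
  expect_error(predict(m, tibble::tibble(x = 2, y = 2)), "out of domain")
})

test_that("interpolation agrees with an established scattered-interpolation library", {
  set.seed(8)
  pts <- rand_points(15)
  z <- sin(3 * pts$x) + cos(2 * pts$y)
  m <- build_model(pts, z, c(0, 1, 0, 1))
  q <- rand_points(80)
  ref <- interp::interpp(pts$x, pts$y, z, q$x, q$y)$z
  ours <- as.vector(predict(m, q))
  inhull <- !is.na(ref)
  expect_gt(sum(inhull), 20)
  expect_equal(ours[inhull], ref[inhull], tolerance = 1e-8)
})

test_that("clipped Voronoi cells conserve area and match independent references", {
  dom <- c(0, 2, 0, 1)
  one <- voronoi_partition(tibble::tibble(x = 0.3, y = 0.8), dom)
  expect_equal(one$areas, 2)

  two <- voronoi_partition(tibble::tibble(x = c(0.5, 1.5), y = c(0.3, 0.3)), dom)
  expect_equal(two$areas, c(1, 1))

  set.seed(9)
  pts <- rand_points(7, dom)
  part <- voronoi_partition(pts, dom)
  expect_equal(sum(part$areas), 2, tolerance = 1e-6)
  mc <- mc_voronoi_areas(pts, dom)
  expect_equal(part$areas, mc, tolerance = 1e-2)

  dd <- deldir::deldir(pts$x, pts$y, rw = dom)
  expect_equal(part$areas, dd$summary$dir.area, tolerance = 1e-5)

  for (n in c(1, 2, 5, 12, 20)) {
    p <- rand_points(n, dom)
    expect_equal(sum(voronoi_partition(p, dom)$areas), 2, tolerance = 1e-6)
  }
  expect_error(voronoi_partition(pts[c(1, 1, 2), ], dom), "duplicate point")
  expect_error(voronoi_partition(tibble::tibble(x = 5, y = 5), dom),
               "inside the domain")
})

test_that("leave-one-out errors vanish for affine data and match the rebuild oracle", {
  set.seed(10)
  pts <- rand_points(9)
  affine <- cbind(pts$x + 2 * pts$y, 3 * pts$x - pts$y)
  eps <- loo_errors(pts, affine)
  hull <- chull(pts$x, pts$y)
  interior <- setdiff(seq_len(9), hull)
  expect_gt(length(interior), 0)
  expect_lt(max(eps[interior]), 1e-9)

  expect_equal(loo_errors(pts, rep(2, 9)), rep(0, 9))

  pts6 <- rand_points(6)
  vals6 <- matrix(rnorm(12), 6, 2)
  expect_identical(loo_errors(pts6, vals6), oracle_loo(pts6, vals6))

  # removing the only off-line point leaves collinear support: nearest fallback
  line <- tibble::tibble(x = c(0, 1, 2, 1), y = c(0, 1, 2, 0))
  vline <- matrix(c(1, 2, 3, 9), 4, 1)
  expect_identical(loo_errors(line, vline), oracle_loo(line, vline))

  expect_error(loo_errors(pts6[1:3, ], vals6[1:3, ]), "at least 4")
})

test_that("min-max normalization, LIV regularization and the weighted mean obey their formulas", {
  expect_equal(normalize_minmax(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_minmax(rep(3, 5)), rep(0, 5))
  set.seed(11)
  x <- rnorm(20)
  s <- normalize_minmax(x)
  expect_equal(s[which.min(x)], 0)
  expect_equal(s[which.max(x)], 1)
  expect_identical(order(s), order(x))

  expect_equal(regularized_errors(c(1, 3), c(4, 2)), c(1, 1))
  set.seed(12)
  e <- runif(15)
  a <- runif(15)
  r <- regularized_errors(e, a)
  expect_true(all(r >= 0 & r <= 2))
  # the extremes are attained only at joint extrema
  e2 <- c(0, 0.5, 1)
  a2 <- c(5, 7, 9)
  expect_equal(regularized_errors(e2, a2), c(0, 1, 2))
  expect_false(any(regularized_errors(c(0, 1, 0.5), c(9, 5, 7)) %in% c(0, 2)))

  expect_equal(mean_weighted_loo(c(1, 2, 6), rep(3, 3)), 3)
  expect_equal(mean_weighted_loo(c(0.3, 0.6), c(2, 1)), 0.4)
  expect_equal(mean_weighted_loo(rep(0, 4), runif(4, 1, 2)), 0)
  set.seed(13)
  e3 <- runif(10)
  a3 <- runif(10)
  expect_equal(mean_weighted_loo(e3, a3), mean_weighted_loo(e3, 7.3 * a3))
})

test_that("the error table assembles aligned per-point diagnostics", {
  set.seed(14)
  pts <- rand_points(8)
  vals <- matrix(rnorm(16), 8, 2)
  et <- error_table(pts, vals, c(0, 1, 0, 1))
  expect_equal(nrow(et), 8)
  expect_equal(et$eps_loo, loo_errors(pts, vals))
  expect_equal(et$area, voronoi_partition(pts, c(0, 1, 0, 1))$areas)
  expect_equal(et$eps_liv, et$sigma_eps + et$sigma_area)
  expect_true(all(et$sigma_eps >= 0 & et$sigma_eps <= 1))
  expect_true(all(et$eps_liv >= 0 & et$eps_liv <= 2))
})
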