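test_that("ground-truth error is zero at full budget and matches direct summation", {
  m <- make_affine_map(n_row = 5, n_col = 5, n_f = 3)
  full <- build_model(m$positions[c("x", "y")], m$spectra, m$domain)
  expect_lt(ground_truth_error(full, m)$epsilon_gt, 1e-9)

  cm <- make_constant_map()
  tri_pts <- cm$positions[c(1, 5, 21), c("x", "y")]
  cmod <- build_model(tri_pts, cm$spectra[c(1, 5, 21), ], cm$domain)
  expect_lt(ground_truth_error(cmod, cm)$epsilon_gt, 1e-12)

  set.seed(15)
  pos <- expand.grid(x = 1:4, y = 1:4)
  spectra <- matrix(runif(16 * 6), 16, 6)
  hm <- spectral_map(pos, spectra, seq(1000, by = 10, length.out = 6))
  mod <- build_model(hm$positions[c(1, 8, 14), c("x", "y")],
                     hm$spectra[c(1, 8, 14), ], hm$domain)
  # direct per-point accumulation oracle
  acc <- 0
  for (i in seq_len(16)) {
    pred_i <- predict(mod, hm$positions[i, c("x", "y")])
    acc <- acc + sum((pred_i - hm$spectra[i, ])^2)
  }
  gt <- ground_truth_error(mod, hm)
  expect_equal(gt$epsilon_gt, sqrt(acc / 16), tolerance = 1e-12)
  gts <- ground_truth_error(mod, hm, variant = "sum")
  expect_equal(gts$epsilon_gt / gt$epsilon_gt, sqrt(16), tolerance = 1e-12)

  bad <- spectral_map(pos, spectra[, 1:5], seq(1000, by = 10, length.out = 5))
  expect_error(ground_truth_error(mod, bad), "axis mismatch")
})

test_that("points_to_target returns the smallest prefix reaching the target", {
  cm <- make_constant_map(n_row = 6, n_col = 6)
  cfg <- acquisition_config("ur", budget = 36, seed = 21)
  expect_equal(points_to_target(cm, "ur", 0.01, cfg), 3)

  set.seed(16)
  m <- make_affine_map(n_row = 6, n_col = 6, n_f = 3)
  # perturb so the field is not exactly affine
  m$spectra <- m$spectra + matrix(rnorm(length(m$spectra), sd = 0.3),
                                  nrow(m$spectra))
  cfg <- acquisition_config("ur", budget = 36, seed = 22)
  # prefix-scan oracle over the same seeded UR sequence
  set.seed(22)
  seq_pts <- uniform_random_points(m$domain, 36)
  gt_at <- function(n) {
    idx <- livsampler:::nearest_grid_index(m, seq_pts$x[1:n], seq_pts$y[1:n])
    livsampler:::prefix_gt(seq_pts$x[1:n], seq_pts$y[1:n],
                           m$spectra[idx, , drop = FALSE], m)
  }
  # a target the sequence provably attains part-way through the scan
  target <- gt_at(20)
  n_s <- points_to_target(m, "ur", target, cfg)
  oracle_n <- NA
  for (n in 3:36) {
    if (gt_at(n) <= target) { oracle_n <- n; break }
  }
  expect_equal(n_s, oracle_n)
  expect_lte(n_s, 20)

  # a strategy always reaches the error of its own full-budget interpolation
  own <- gt_at(30)
  expect_lte(points_to_target(m, "ur", own, cfg), 30)

  expect_error(points_to_target(m, "ur", 1e-9, cfg), "target unreachable")
  expect_error(points_to_target(m, "ur", -1, cfg), "epsilon_target")
})

test_that("benchmark ratios are 1 for UG against itself and reruns are identical", {
  set.seed(17)
  ax <- seq(1000, 1500, by = 50)
  comp <- component_spec("c", data.frame(center = 1200, width = 30, height = 1))
  blob <- data.frame(x = 4, y = 5, sx = 1.5, sy = 1.5, amplitude = 1)
  m <- generate_map(list(comp), list(blob), axis = ax, n_row = 10, n_col = 10,
                    step = 1, noise_sd = 0.001, seed = 3)
  cfg <- acquisition_config("liv", budget = 100, n_init = 6, seed = 1)
  bm <- benchmark_compare(m, strategies = c("ug", "ur"), replicates = 3,
                          seed = 30, k = 2, config = cfg)
  expect_true(all(bm$ratio[bm$strategy == "ug"] == 1))
  bm2 <- benchmark_compare(m, strategies = c("ug", "ur"), replicates = 3,
                           seed = 30, k = 2, config = cfg)
  expect_identical(bm, bm2)
  s <- summarize_benchmark(bm)
  expect_setequal(s$strategy, c("ug", "ur"))
})

test_that("peak criteria are the mean intensities of the reference set", {
  ax <- seq(650, 4000, by = 50)
  one <- exp(-0.5 * ((ax - 800) / 30)^2)
  same <- sample_set(rand_points(3), rbind(one, one, one), ax)
  crit <- derive_peak_criteria(same, 800)
  expect_equal(crit$threshold, one[which.min(abs(ax - 800))])

  two <- sample_set(rand_points(2), rbind(0.2 * one / max(one),
                                          0.4 * one / max(one)), ax)
  crit2 <- derive_peak_criteria(two, 800)
  expect_equal(crit2$threshold, 0.3, tolerance = 1e-12)

  set.seed(18)
  mat <- matrix(runif(50 * length(ax)), 50)
  many <- sample_set(rand_points(50), mat, ax)
  ws <- c(798, 1580, 2900)
  crit3 <- derive_peak_criteria(many, ws)
  idx <- vapply(ws, function(w) which.min(abs(ax - w)), integer(1))
  expect_equal(crit3$threshold, colMeans(mat[, idx]), ignore_attr = TRUE)
  expect_equal(crit3$wavenumber, ax[idx])
})

test_that("the on-target ratio counts inclusive-OR criterion hits", {
  ax <- seq(650, 4000, by = 50)
  n <- 40
  mat <- matrix(0, n, length(ax))
  i1 <- which.min(abs(ax - 798))
  i2 <- which.min(abs(ax - 1580))
  mat[1:10, i1] <- 1       # first criterion only
  mat[11:18, i2] <- 1      # second criterion only
  mat[19:22, c(i1, i2)] <- 1  # both
  set <- sample_set(rand_points(n), mat, ax)
  crit <- tibble::tibble(wavenumber = c(798, 1580), threshold = c(0.5, 0.5))
  expect_equal(otr(set, crit), 22 / 40)
  expect_equal(otr(set, crit[1, ]), 14 / 40)
  # nothing on-target
  expect_equal(otr(set, tibble::tibble(wavenumber = 798, threshold = 99)), 0)
  # adding an on-target spectrum never decreases the hit count
  set2 <- sample_set(rbind(set$points[c("x", "y")],
                           tibble::tibble(x = 0.99, y = 0.99)),
                     rbind(mat, 1), ax)
  expect_gte(otr(set2, crit) * 41, otr(set, crit) * 40)
})
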