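#' Deterministic cell-centred uniform grid
#'
#' The UG baseline measures a static rectangular grid. The `r x c` layout is
#' chosen among factorizations with `r * c <= budget` by first maximizing the
#' point count and then matching the grid aspect ratio to the domain's;
#' points are cell centres, emitted in row-major (raster) order.
#'
#' @param domain rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param budget maximum number of points (>= 1).
#' @return Tibble of points with columns `x`, `y`.
#' @examples
#' uniform_grid_points(c(0, 1, 0, 1), 9)  # 3 x 3 centred grid
#' @export
uniform_grid_points <- function(domain, budget) {
  domain <- as_domain(domain)
  check_scalar_number(budget, "budget", min = 1)
  budget <- as.integer(budget)
  w <- domain[[2]] - domain[[1]]
  h <- domain[[4]] - domain[[3]]
  r_cand <- seq_len(budget)
  c_cand <- floor(budget / r_cand)
  n_cand <- r_cand * c_cand
  best_n <- max(n_cand)
  keep <- which(n_cand == best_n)
  score <- abs(log((c_cand[keep] / r_cand[keep]) / (w / h)))
  pick <- keep[which.min(score)]
  r <- r_cand[pick]
  cc <- c_cand[pick]
  xs <- domain[[1]] + (seq_len(cc) - 0.5) * w / cc
  ys <- domain[[3]] + (seq_len(r) - 0.5) * h / r
  tibble::tibble(x = rep(xs, times = r), y = rep(ys, each = cc))
}

#' Offset subgrids of a raster map
#'
#' Selecting every k-th point of the full-resolution raster produces a lower
#' resolution grid with roughly 1/k^2 of the points; shifting the first
#' selected point yields all k^2 possible subgrids. These are the UG
#' subsampling inputs of the simulation benchmark.
#'
#' @param map a [spectral_map()].
#' @param k subsampling factor (`1 <= k <= min(rows, cols)`).
#' @return List of k^2 tibbles with columns `x`, `y`, `index` (row index into
#'   `map$positions`), ordered row-major over (row offset, column offset).
#' @export
subgrids <- function(map, k) {
  stopifnot(inherits(map, "spectral_map"))
  check_scalar_number(k, "k", min = 1)
  k <- as.integer(k)
  if (k > min(map$dims)) {
    abort("k exceeds grid", class = "livsampler_error_subgrid")
  }
  pos <- map$positions
  out <- vector("list", k * k)
  i <- 1L
  for (oy in 0:(k - 1)) {
    for (ox in 0:(k - 1)) {
      sel <- which((pos$row - 1L) %% k == oy & (pos$col - 1L) %% k == ox)
      out[[i]] <- tibble::tibble(x = pos$x[sel], y = pos$y[sel], index = sel)
      i <- i + 1L
    }
  }
  out
}

#' Uniform random points in the domain
#'
#' @param domain rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param n number of points.
#' @param seed optional RNG seed; `NULL` draws from the current RNG stream
#'   (so a surrounding `set.seed()` still makes the run reproducible).
#' @return Tibble of points with columns `x`, `y`.
#' @export
uniform_random_points <- function(domain, n, seed = NULL) {
  domain <- as_domain(domain)
  check_scalar_number(n, "n", min = 1)
  local_seed(seed, {
    tibble::tibble(
      x = runif(n, domain[[1]], domain[[2]]),
      y = runif(n, domain[[3]], domain[[4]])
    )
  })
}

# uniform random point inside cell `i` of a Voronoi partition: rejection
# sampling from the cell's bounding box with a nearest-owner membership test
# (cap 1e4 trials, then the cell centroid as a deterministic fallback)
sample_in_cell <- function(partition, i, max_trials = 1e4) {
  poly <- partition$polygons[[i]]
  bx <- range(poly[, 1])
  by <- range(poly[, 2])
  px <- partition$points$x
  py <- partition$points$y
  trials <- 0L
  chunk <- 64L
  while (trials < max_trials) {
    m <- min(chunk, max_trials - trials)
    cx <- runif(m, bx[1], bx[2])
    cy <- runif(m, by[1], by[2])
    owner <- cpp_nearest_index(px, py, cx, cy)
    hit <- which(owner == i)
    if (length(hit) > 0) {
      return(c(x = cx[hit[1]], y = cy[hit[1]]))
    }
    trials <- trials + m
  }
  centroid <- polygon_centroid(poly)
  # a centroid could (rarely) coincide with an existing point; nudge inward
  if (any(px == centroid[1] & py == centroid[2])) {
    centroid <- centroid + 0.5 * (poly[1, ] - centroid)
  }
  c(x = centroid[[1]], y = centroid[[2]])
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  x2 <- c(x[-1], x[1])
  y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr) / (6 * a), sum((y + y2) * cr) / (6 * a))
}

#' Next point for the largest-unexplored-region (LUR) baseline
#'
#' LUR measures in the most sparsely sampled region: a uniform random point
#' inside the largest boundary-clipped Voronoi cell of the points measured so
#' far (ties broken by lowest owner index).
#'
#' @param points data frame (columns `x`, `y`) of existing points.
#' @param domain rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param seed optional RNG seed (`NULL`: current stream).
#' @return Named numeric `c(x, y)`.
#' @export
lur_next_point <- function(points, domain, seed = NULL) {
  part <- voronoi_partition(points, domain)
  i <- which.max(part$areas)
  local_seed(seed, sample_in_cell(part, i))
}

#' Next point for the LIV strategy
#'
#' Draws a uniform random point inside the Voronoi cell of the point with the
#' highest regularized LIV error (ties broken by lowest index).
#'
#' @param errors an [error_table()] (or any data frame with an `eps_liv`
#'   column aligned with `partition`).
#' @param partition the matching [voronoi_partition()].
#' @param seed optional RNG seed (`NULL`: current stream).
#' @return Named numeric `c(x, y)`.
#' @export
liv_next_point <- function(errors, partition, seed = NULL) {
  if (nrow(errors) != length(partition$areas)) {
    abort("`errors` and `partition` must be aligned")
  }
  i <- which.max(errors$eps_liv)
  local_seed(seed, sample_in_cell(partition, i))
}

#' Acquisition configuration
#'
#' @param strategy one of `"liv"`, `"lur"`, `"ur"`, `"ug"` (case-insensitive).
#' @param budget total number of points to acquire (stop criterion;
#'   default 500).
#' @param n_init number of initial uniformly random points for the adaptive
#'   strategies (default 10; `budget >= n_init >= 3`).
#' @param seed RNG seed; the whole run is reproducible from (config, seed).
#' @param band optional wavenumber band `c(low, high)` restricting spectra
#'   before surrogate construction (e.g. `c(900, 3700)`).
#' @param n_components PCA components retained for the LIV error calculation
#'   (default 5).
#' @param baseline apply rubber-band baseline correction before PCA
#'   (default TRUE).
#' @param k uniform-grid subsampling factor used by the simulation benchmark.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(strategy = c("liv", "lur", "ur", "ug"),
                               budget = 500, n_init = 10, seed = 1L,
                               band = NULL, n_components = 5,
                               baseline = TRUE, k = 2) {
  strategy <- tolower(strategy)
  strategy <- match.arg(strategy)
  check_scalar_number(budget, "budget", min = 1)
  check_scalar_number(n_init, "n_init", min = 3)
  check_scalar_number(n_components, "n_components", min = 1)
  check_scalar_number(k, "k", min = 1)
  if (strategy %in% c("liv", "lur") && budget < n_init) {
    abort("`budget` must be >= `n_init` for adaptive strategies")
  }
  if (!is.null(band)) band <- as_band(band)
  structure(
    list(strategy = strategy, budget = as.integer(budget),
         n_init = as.integer(n_init), seed = as.integer(seed),
         band = band, n_components = n_components,
         baseline = isTRUE(baseline), k = as.integer(k)),
    class = "acquisition_config"
  )
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "<acquisition_config> %s, budget %d, n_init %d, seed %d, pca %d%s\n",
    toupper(x$strategy), x$budget, x$n_init, x$seed, x$n_components,
    if (is.null(x$band)) "" else sprintf(", band %g-%g", x$band[1], x$band[2])))
  invisible(x)
}

#' Run an autonomous acquisition loop against an instrument
#'
#' Executes the full sampling workflow. UG measures its grid in raster order
#' and UR measures `budget` uniform random points. The adaptive strategies
#' (LUR, LIV) first measure `n_init` random points, then iterate: preprocess
#' all acquired spectra (band restriction, rubber-band baseline, PCA), build
#' the surrogate, compute the per-point error table (LIV) or Voronoi areas
#' (LUR), pick the next point, and measure it -- until `budget` points have
#' been acquired. Every adaptive iteration appends an audit record with the
#' chosen point, the error tables and the Voronoi-weighted mean LOO error.
#'
#' An instrument failure propagates as a classed error
#' (`livsampler_error_instrument`) carrying the partial sample set acquired
#' so far in its `sample_set` field.
#'
#' @param instrument an instrument object (see [simulated_instrument()]):
#'   list with `measure(x, y)`, `domain`, `axis`.
#' @param config an [acquisition_config()].
#' @return An object of class `acquisition`: list with `sample_set`, `audit`
#'   (tibble, one row per measured point) and `config`.
#' @export
run_acquisition <- function(instrument, config) {
  stopifnot(inherits(config, "acquisition_config"))
  domain <- as_domain(instrument$domain)
  set.seed(config$seed)
  run <- acquire_loop(instrument$measure, domain, instrument$axis, config,
                      max_points = config$budget)
  finish_acquisition(run, instrument$axis, domain, config)
}

finish_acquisition <- function(run, axis, domain, config) {
  set <- sample_set(run$points, run$raw, axis, domain = domain,
                    seed = config$seed)
  structure(list(sample_set = set, audit = run$audit, config = config),
            class = "acquisition")
}

#' @export
print.acquisition <- function(x, ...) {
  final <- x$audit$mean_weighted_loo
  final <- final[!is.na(final)]
  cat(sprintf("<acquisition> %s, %d points%s\n",
              toupper(x$config$strategy), nrow(x$sample_set$points),
              if (length(final)) sprintf(", final <eps_LOO>_V = %.4g",
                                         final[length(final)]) else ""))
  invisible(x)
}

# The shared engine behind run_acquisition() and points_to_target().
# `after_step(n, px, py, raw)` is called after every measured point with the
# current prefix; returning TRUE stops the run early (epsilon_GT scans).
acquire_loop <- function(measure, domain, axis, config, max_points,
                         after_step = NULL) {
  strategy <- config$strategy
  band_idx <- if (is.null(config$band)) seq_along(axis)
              else band_indices(axis, config$band)
  if (length(band_idx) == 0) abort("empty band", class = "livsampler_error_band")
  axis_r <- axis[band_idx]

  pts_x <- numeric(0)
  pts_y <- numeric(0)
  raw <- NULL     # acquired spectra, full axis
  proc <- NULL    # band-restricted (+ baseline-corrected) spectra
  audit <- list()

  measure_safe <- function(x, y) {
    tryCatch(measure(x, y), error = function(e) {
      partial <- sample_set(tibble::tibble(x = pts_x, y = pts_y),
                            if (is.null(raw)) {
                              matrix(0, 0, length(axis))
                            } else raw,
                            axis, domain = domain, seed = config$seed)
      abort("instrument failure", class = "livsampler_error_instrument",
            parent = e, sample_set = partial)
    })
  }

  add_point <- function(x, y, record) {
    sp <- measure_safe(x, y)
    pts_x[length(pts_x) + 1L] <<- x
    pts_y[length(pts_y) + 1L] <<- y
    raw <<- rbind(raw, sp)
    p <- sp[band_idx]
    if (config$baseline) p <- rubberband_one(axis_r, p)
    proc <<- rbind(proc, p)
    record$n_s <- length(pts_x)
    audit[[length(audit) + 1L]] <<- record
  }

  stopped <- FALSE
  emit <- function() {
    n <- length(pts_x)
    if (!is.null(after_step) && isTRUE(after_step(n, pts_x, pts_y, raw))) {
      stopped <<- TRUE
    }
    stopped || n >= max_points
  }

  if (strategy %in% c("ug", "ur")) {
    pts <- if (strategy == "ug") uniform_grid_points(domain, max_points)
           else uniform_random_points(domain, max_points)
    for (i in seq_len(nrow(pts))) {
      add_point(pts$x[i], pts$y[i],
                list(iteration = i, x = pts$x[i], y = pts$y[i],
                     mean_weighted_loo = NA_real_))
      if (emit()) break
    }
  } else {
    init <- uniform_random_points(domain, min(config$n_init, max_points))
    done <- FALSE
    for (i in seq_len(nrow(init))) {
      add_point(init$x[i], init$y[i],
                list(iteration = i, x = init$x[i], y = init$y[i],
                     mean_weighted_loo = NA_real_))
      if (emit()) { done <- TRUE; break }
    }
    while (!done) {
      n <- length(pts_x)
      pts <- tibble::tibble(x = pts_x, y = pts_y)
      part <- voronoi_partition(pts, domain)
      if (strategy == "liv") {
        scores <- pca_scores(proc, config$n_components)$scores
        eps <- loo_errors_impl(pts, scores)
        sig_e <- normalize_minmax(eps)
        sig_v <- normalize_minmax(part$areas)
        eps_liv <- sig_e + sig_v
        mloo <- mean_weighted_loo(eps, part$areas)
        i_next <- which.max(eps_liv)
        np <- sample_in_cell(part, i_next)
        record <- list(iteration = n + 1L, x = np[["x"]], y = np[["y"]],
                       mean_weighted_loo = mloo,
                       eps_loo = list(eps), eps_liv = list(eps_liv),
                       areas = list(part$areas))
      } else {
        i_next <- which.max(part$areas)
        np <- sample_in_cell(part, i_next)
        record <- list(iteration = n + 1L, x = np[["x"]], y = np[["y"]],
                       mean_weighted_loo = NA_real_,
                       areas = list(part$areas))
      }
      add_point(np[["x"]], np[["y"]], record)
      done <- emit()
    }
  }

  audit_tbl <- dplyr::bind_rows(lapply(audit, function(r) {
    tibble::tibble(
      iteration = r$iteration, x = r$x, y = r$y, n_s = r$n_s,
      mean_weighted_loo = r$mean_weighted_loo,
      eps_loo = if (is.null(r$eps_loo)) list(NULL) else r$eps_loo,
      eps_liv = if (is.null(r$eps_liv)) list(NULL) else r$eps_liv,
      areas = if (is.null(r$areas)) list(NULL) else r$areas
    )
  }))
  list(points = tibble::tibble(x = pts_x, y = pts_y), raw = raw,
       proc = proc, audit = audit_tbl)
}

#' Serialize an acquisition audit log as JSON lines
#'
#' One JSON record per measured point (iteration, chosen point, error tables
#' where the strategy computes them, Voronoi-weighted mean LOO error).
#' Bit-identical logs across reruns with the same (config, seed) certify
#' reproducibility.
#'
#' @param acquisition a [run_acquisition()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_audit_log <- function(acquisition, path) {
  stopifnot(inherits(acquisition, "acquisition"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  aud <- acquisition$audit
  for (i in seq_len(nrow(aud))) {
    rec <- list(
      iteration = aud$iteration[i],
      point = c(aud$x[i], aud$y[i]),
      n_s = aud$n_s[i],
      mean_weighted_loo = aud$mean_weighted_loo[i]
    )
    if (!is.null(aud$eps_loo[[i]])) {
      rec$eps_loo <- aud$eps_loo[[i]]
      rec$eps_liv <- aud$eps_liv[[i]]
    }
    if (!is.null(aud$areas[[i]])) rec$areas <- aud$areas[[i]]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}
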