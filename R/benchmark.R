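#' Ground-truth error of a surrogate against a full-resolution map
#'
#' Evaluates the surrogate at every grid point of the reference map and
#' aggregates the per-point L2 spectral discrepancies. The default `"rmse"`
#' variant is `sqrt(mean_i ||U(X_i) - Y_i||^2)`; the `"sum"` variant omits
#' the 1/N0 factor (the two differ exactly by `sqrt(N0)` and give identical
#' strategy rankings on a fixed map).
#'
#' @param model a [build_model()] surrogate whose values live in the map's
#'   spectral representation and whose domain covers the map grid.
#' @param map the ground-truth [spectral_map()].
#' @param variant `"rmse"` (default) or `"sum"`.
#' @return One-row tibble with columns `epsilon_gt`, `n0`, `variant`.
#' @export
ground_truth_error <- function(model, map, variant = c("rmse", "sum")) {
  stopifnot(inherits(model, "surrogate_model"), inherits(map, "spectral_map"))
  variant <- match.arg(variant)
  if (ncol(model$values) != length(map$axis)) {
    abort("axis mismatch", class = "livsampler_error_axis")
  }
  pred <- predict(model, map$positions[c("x", "y")])
  total <- sum((pred - map$spectra)^2)
  n0 <- nrow(map$positions)
  value <- if (variant == "rmse") sqrt(total / n0) else sqrt(total)
  tibble::tibble(epsilon_gt = value, n0 = n0, variant = variant)
}

# epsilon_GT of a point prefix (positions + spectra) against a map;
# Inf when the support is not yet buildable (e.g. first points collinear)
prefix_gt <- function(px, py, spectra, map, variant = "rmse") {
  model <- tryCatch(
    build_model(tibble::tibble(x = px, y = py), spectra, domain = map$domain),
    error = function(e) NULL
  )
  if (is.null(model)) return(Inf)
  ground_truth_error(model, map, variant)$epsilon_gt
}

#' Points needed for a strategy to reach a target ground-truth error
#'
#' Grows the strategy's own acquisition sequence one point at a time (spectra
#' drawn from the map by nearest-grid lookup, as in the simulation design)
#' and returns the smallest sampled count whose interpolation attains
#' `epsilon_gt <= epsilon_target`. For the adaptive strategies the sequence
#' is generated by the same loop as [run_acquisition()]; the ground-truth
#' error is always computed on the full (band-restricted) spectra so the
#' comparison representation is identical across strategies, with LIV's
#' internal PCA used only for point selection.
#'
#' @param map ground-truth [spectral_map()].
#' @param strategy `"ug"`, `"ur"`, `"lur"` or `"liv"` (overrides the config).
#' @param epsilon_target positive target value (rmse variant).
#' @param config an [acquisition_config()]; its `seed`, `band`, `n_init`,
#'   `n_components` and `baseline` settings drive the run.
#' @param max_points scan cap; defaults to the number of map grid points.
#' @return Smallest `N_s` reaching the target (integer). Errors with
#'   "target unreachable" if the cap is hit first.
#' @export
points_to_target <- function(map, strategy, epsilon_target, config,
                             max_points = NULL) {
  stopifnot(inherits(map, "spectral_map"))
  strategy <- tolower(strategy)
  check_scalar_number(epsilon_target, "epsilon_target")
  if (epsilon_target <= 0) abort("`epsilon_target` must be > 0")
  config$strategy <- strategy
  map_r <- if (is.null(config$band)) map else restrict_band(map, config$band)
  cap <- if (is.null(max_points)) nrow(map_r$positions) else as.integer(max_points)
  if (strategy == "ug") cap <- min(cap, config$budget)
  instrument <- simulated_instrument(map_r)
  found <- NA_integer_
  set.seed(config$seed)
  # band already applied to the map feeding the instrument
  cfg <- config
  cfg$band <- NULL
  acquire_loop(
    instrument$measure, map_r$domain, map_r$axis, cfg, max_points = cap,
    after_step = function(n, px, py, raw) {
      if (n < 3) return(FALSE)
      e <- prefix_gt(px, py, raw, map_r)
      if (e <= epsilon_target) {
        found <<- n
        TRUE
      } else {
        FALSE
      }
    }
  )
  if (is.na(found)) {
    abort("target unreachable", class = "livsampler_error_unreachable")
  }
  found
}

#' Compare sampling strategies on ground-truth maps
#'
#' The simulation benchmark design: on each map the UG target is the mean
#' ground-truth error over all k^2 offset subgrids at the UG budget; every
#' other strategy is then grown until it reaches that target, and its point
#' count is reported as a ratio to the UG subgrid size. UG itself reports
#' ratio 1 by construction. Per-replicate seeds are derived deterministically
#' from `seed`, so the whole benchmark is reproducible.
#'
#' @param maps a [spectral_map()] or list of maps.
#' @param strategies character vector among `"ug"`, `"ur"`, `"lur"`, `"liv"`.
#' @param replicates stochastic replicates per (map, strategy).
#' @param seed base RNG seed.
#' @param k UG subsampling factor (the UG budget is ~N0/k^2).
#' @param config an [acquisition_config()] supplying `band`, `n_init`,
#'   `n_components`, `baseline` for the adaptive strategies.
#' @param aggregate how the k^2 subgrid errors define the target
#'   (`"mean"`, `"median"`).
#' @return Tibble of class `benchmark_result` with one row per
#'   (map, strategy, replicate): columns `map`, `strategy`, `replicate`,
#'   `n_s`, `n_ug`, `target`, `ratio`. `n_s` is `NA` when the target was
#'   unreachable within the map.
#' @export
benchmark_compare <- function(maps, strategies = c("ug", "ur", "lur", "liv"),
                              replicates = 1, seed = 1L, k = 2,
                              config = acquisition_config("liv", budget = 500),
                              aggregate = c("mean", "median")) {
  if (inherits(maps, "spectral_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1, replicates >= 1)
  strategies <- tolower(strategies)
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "mean") mean else stats::median
  grid <- expand.grid(
    map = seq_along(maps), strategy = strategies,
    replicate = seq_len(replicates),
    stringsAsFactors = FALSE
  )
  set.seed(seed)
  grid$run_seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (mi in seq_along(maps)) {
    map <- maps[[mi]]
    map_r <- if (is.null(config$band)) map else restrict_band(map, config$band)
    subs <- subgrids(map_r, k)
    sub_gt <- vapply(subs, function(s) {
      prefix_gt(s$x, s$y, map_r$spectra[s$index, , drop = FALSE], map_r)
    }, numeric(1))
    target <- agg_fun(sub_gt)
    n_ug <- mean(vapply(subs, nrow, integer(1)))
    sel <- which(grid$map == mi)
    for (gi in sel) {
      strat <- grid$strategy[gi]
      if (strat == "ug") {
        n_s <- n_ug
      } else {
        cfg <- config
        cfg$seed <- grid$run_seed[gi]
        cfg$budget <- nrow(map_r$positions)
        n_s <- tryCatch(
          points_to_target(map, strat, target, cfg),
          livsampler_error_unreachable = function(e) NA_integer_
        )
      }
      rows[[gi]] <- tibble::tibble(
        map = mi, strategy = strat, replicate = grid$replicate[gi],
        n_s = as.numeric(n_s), n_ug = n_ug, target = target,
        ratio = as.numeric(n_s) / n_ug
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("benchmark_result", class(out))
  out
}

#' Summarize a benchmark by strategy
#'
#' @param result a [benchmark_compare()] result.
#' @return Tibble with one row per strategy: `median_ratio`,
#'   `frac_outperform` (fraction of replicates with ratio < 1; unreachable
#'   runs count as not outperforming), `n_runs`.
#' @export
summarize_benchmark <- function(result) {
  stopifnot(inherits(result, "benchmark_result"))
  dplyr::summarise(
    dplyr::group_by(result, .data$strategy),
    median_ratio = stats::median(.data$ratio, na.rm = TRUE),
    frac_outperform = mean(!is.na(.data$ratio) & .data$ratio < 1),
    n_runs = dplyr::n(),
    .groups = "drop"
  )
}

#' Derive on-target peak criteria from reference spectra
#'
#' For each requested wavenumber (snapped to the nearest axis point) the
#' threshold is the mean intensity of the supplied (noise-filtered) spectra
#' at that axis point -- the "noise-removed mean intensity at defined
#' frequencies" rule.
#'
#' @param standards a non-empty, typically noise-filtered [sample_set()].
#' @param wavenumbers numeric vector of peak positions (cm^-1).
#' @return Tibble with columns `wavenumber` (snapped) and `threshold`.
#' @export
derive_peak_criteria <- function(standards, wavenumbers) {
  stopifnot(inherits(standards, "sample_set"))
  if (nrow(standards$points) == 0) {
    abort("no spectra", class = "livsampler_error_empty")
  }
  idx <- vapply(wavenumbers, function(w) which.min(abs(standards$axis - w)),
                integer(1))
  tibble::tibble(
    wavenumber = standards$axis[idx],
    threshold = colMeans(standards$spectra[, idx, drop = FALSE])
  )
}

#' On-target ratio of an acquired sample set
#'
#' The fraction of acquired spectra whose intensity meets or exceeds the
#' threshold at any criterion wavenumber (inclusive OR over criteria):
#' `OTR = N_match / N_total`.
#'
#' @param set a [sample_set()].
#' @param criteria tibble from [derive_peak_criteria()] (columns
#'   `wavenumber`, `threshold`).
#' @return A single number in `[0, 1]`.
#' @examples
#' # 474 of 500 spectra on-target gives OTR = 0.948
#' @export
otr <- function(set, criteria) {
  stopifnot(inherits(set, "sample_set"))
  if (nrow(set$points) == 0) abort("no spectra", class = "livsampler_error_empty")
  if (!is.data.frame(criteria) || nrow(criteria) < 1 ||
      !all(c("wavenumber", "threshold") %in% names(criteria))) {
    abort("`criteria` needs at least one row with `wavenumber`, `threshold`")
  }
  idx <- vapply(criteria$wavenumber,
                function(w) which.min(abs(set$axis - w)), integer(1))
  hit <- rep(FALSE, nrow(set$points))
  for (j in seq_along(idx)) {
    hit <- hit | (set$spectra[, idx[j]] >= criteria$threshold[j])
  }
  sum(hit) / length(hit)
}
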