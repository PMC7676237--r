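# broom-style tidiers for the package's fitted/derived objects

#' @export
tidy.surrogate_model <- function(x, ...) {
  vals <- tibble::as_tibble(x$values, .name_repair = function(nm) {
    if (all(nm == "")) paste0("value_", seq_along(nm)) else nm
  })
  dplyr::bind_cols(x$points, vals)
}

#' @export
glance.surrogate_model <- function(x, ...) {
  tibble::tibble(
    n_support = nrow(x$points),
    n_dim = ncol(x$values),
    n_triangles = nrow(x$triangles),
    domain_area = domain_area(x$domain)
  )
}

#' @export
tidy.voronoi_partition <- function(x, ...) {
  tibble::tibble(
    point = seq_along(x$areas),
    x = x$points$x,
    y = x$points$y,
    area = x$areas,
    n_vertices = vapply(x$polygons, nrow, integer(1))
  )
}

#' @export
glance.voronoi_partition <- function(x, ...) {
  tibble::tibble(
    n_cells = length(x$areas),
    total_area = sum(x$areas),
    domain_area = domain_area(x$domain),
    min_area = min(x$areas),
    max_area = max(x$areas)
  )
}

#' @export
tidy.acquisition <- function(x, ...) {
  x$audit[c("iteration", "x", "y", "n_s", "mean_weighted_loo")]
}

#' @export
glance.acquisition <- function(x, ...) {
  mloo <- x$audit$mean_weighted_loo
  mloo <- mloo[!is.na(mloo)]
  tibble::tibble(
    strategy = x$config$strategy,
    n_points = nrow(x$sample_set$points),
    n_init = x$config$n_init,
    seed = x$config$seed,
    final_mean_weighted_loo = if (length(mloo)) mloo[length(mloo)] else NA_real_
  )
}

#' @export
tidy.reduced_sample_set <- function(x, ...) {
  scores <- tibble::as_tibble(x$scores, .name_repair = "minimal")
  names(scores) <- paste0("PC", seq_len(ncol(scores)))
  dplyr::bind_cols(x$points, scores)
}

#' @export
glance.reduced_sample_set <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$points),
    n_components = x$n_components,
    total_explained_variance = sum(x$explained_variance)
  )
}

#' @export
glance.benchmark_result <- function(x, ...) {
  tibble::tibble(
    n_maps = dplyr::n_distinct(x$map),
    n_strategies = dplyr::n_distinct(x$strategy),
    n_replicates = dplyr::n_distinct(x$replicate)
  )
}
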