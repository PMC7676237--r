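#' Build a scattered-data linear interpolation surrogate
#'
#' Fits the piecewise-linear surrogate used throughout the adaptive loop:
#' a Delaunay triangulation of the support points with barycentric linear
#' interpolation inside each triangle, applied independently to every value
#' dimension (PCA score or spectral channel). Queries outside the convex hull
#' of the support fall back to the value of the nearest support point, which
#' keeps leave-one-out errors finite at hull vertices.
#'
#' @param points data frame (columns `x`, `y`) or two-column matrix of
#'   support positions; at least 3 non-collinear points.
#' @param values numeric vector or matrix (one row per point, one column per
#'   value dimension).
#' @param domain rectangle `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   bounding box of the points, padded so every point is interior.
#' @return An object of class `surrogate_model`.
#' @examples
#' pts <- data.frame(x = runif(8), y = runif(8))
#' m <- build_model(pts, 2 * pts$x - pts$y + 3, domain = c(0, 1, 0, 1))
#' predict(m, data.frame(x = 0.5, y = 0.5))
#' @export
build_model <- function(points, values, domain = NULL) {
  points <- as_points_tbl(points)
  values <- as_values_matrix(values, nrow(points))
  if (is.null(domain)) {
    pad_x <- max(diff(range(points$x)), 1e-6) * 0.01
    pad_y <- max(diff(range(points$y)), 1e-6) * 0.01
    domain <- c(min(points$x) - pad_x, max(points$x) + pad_x,
                min(points$y) - pad_y, max(points$y) + pad_y)
  }
  domain <- as_domain(domain)
  if (!all(in_domain(points$x, points$y, domain))) {
    abort("all support points must lie inside the domain",
          class = "livsampler_error_out_of_domain")
  }
  if (nrow(points) < 3) {
    abort("degenerate support", class = "livsampler_error_degenerate")
  }
  triangles <- tryCatch(
    cpp_triangulate(points$x, points$y),
    error = function(e) {
      msg <- conditionMessage(e)
      if (grepl("duplicate point", msg)) {
        abort("duplicate point", class = "livsampler_error_duplicate")
      }
      abort("degenerate support", class = "livsampler_error_degenerate")
    }
  )
  structure(
    list(points = points, values = values, domain = domain,
         triangles = triangles),
    class = "surrogate_model"
  )
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf(
    "<surrogate_model> %d support points, %d value dimension(s), %d triangles\n",
    nrow(x$points), ncol(x$values), nrow(x$triangles)))
  invisible(x)
}

#' Evaluate a surrogate model at query positions
#'
#' Inside the convex hull of the support, the value is the barycentric
#' combination of the containing Delaunay triangle's vertices; outside the
#' hull (but inside the domain) it is the value of the nearest support point.
#' Querying outside the domain is an error.
#'
#' @param object a [build_model()] surrogate.
#' @param newdata data frame (columns `x`, `y`) or two-column matrix of query
#'   positions inside the model domain.
#' @param ... unused.
#' @return Numeric matrix, one row per query, one column per value dimension.
#' @export
predict.surrogate_model <- function(object, newdata, ...) {
  q <- as_points_tbl(newdata)
  if (!all(in_domain(q$x, q$y, object$domain))) {
    abort("out of domain", class = "livsampler_error_out_of_domain")
  }
  out <- cpp_interp(object$points$x, object$points$y, object$values, q$x, q$y)
  colnames(out) <- colnames(object$values)
  out
}

#' Boundary-clipped Voronoi partition of sampled points
#'
#' Each cell is the intersection of the (possibly unbounded) Voronoi cell --
#' the region of positions closer in Euclidean distance to its owner than to
#' any other sampled point -- with the map rectangle, which gives every cell a
#' finite area. Cell areas proxy local sampling sparsity and sum to the
#' domain area.
#'
#' @param points data frame (columns `x`, `y`) of pairwise-distinct points
#'   inside the domain.
#' @param domain rectangle `c(xmin, xmax, ymin, ymax)`.
#' @return An object of class `voronoi_partition` with fields `points`,
#'   `areas` (um^2), `polygons` (list of CCW vertex matrices) and `domain`.
#' @export
voronoi_partition <- function(points, domain) {
  points <- as_points_tbl(points)
  domain <- as_domain(domain)
  if (nrow(points) < 1) abort("need at least one point")
  if (!all(in_domain(points$x, points$y, domain))) {
    abort("all points must lie inside the domain",
          class = "livsampler_error_out_of_domain")
  }
  vor <- tryCatch(
    cpp_voronoi(points$x, points$y,
                domain[[1]], domain[[2]], domain[[3]], domain[[4]]),
    error = function(e) {
      abort("duplicate point", class = "livsampler_error_duplicate")
    }
  )
  structure(
    list(points = points, areas = vor$areas, polygons = vor$polygons,
         domain = domain),
    class = "voronoi_partition"
  )
}

#' @export
print.voronoi_partition <- function(x, ...) {
  cat(sprintf("<voronoi_partition> %d cells, total area %g um^2\n",
              length(x$areas), sum(x$areas)))
  invisible(x)
}

#' Leave-one-out cross-validation errors of the surrogate
#'
#' For each sampled point i the surrogate is rebuilt from the remaining
#' points and evaluated at the removed position; the error is the L2 distance
#' between the full model's value there (the stored value itself, by the
#' interpolation identity) and the rebuilt model's prediction. If removing a
#' point leaves a degenerate (collinear) support, or the removed position
#' falls outside the reduced hull, the nearest-support fallback supplies the
#' prediction, keeping every error finite.
#'
#' @param points data frame (columns `x`, `y`); at least 4 points so each
#'   leave-one-out model is buildable.
#' @param values numeric vector or matrix of per-point values (PCA scores in
#'   the adaptive loop).
#' @param domain optional rectangle; accepted for interface symmetry (the
#'   errors themselves do not depend on it).
#' @return Numeric vector of per-point errors, in units of the value space.
#' @export
loo_errors <- function(points, values, domain = NULL) {
  points <- as_points_tbl(points)
  if (nrow(points) < 4) {
    abort("need at least 4 points for leave-one-out errors")
  }
  loo_errors_impl(points, values)
}

# permissive core (n >= 3) used by the acquisition loop
loo_errors_impl <- function(points, values) {
  values <- as_values_matrix(values, nrow(points))
  as.numeric(cpp_loo(points$x, points$y, values))
}

#' Min-max normalization to the unit interval
#'
#' Linear scaling `(x - min) / (max - min)` used to place leave-one-out
#' errors and Voronoi areas on a common `[0, 1]` scale before combining them.
#' A constant vector carries no ranking information and maps to all zeros.
#'
#' @param x non-empty numeric vector of finite values.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_minmax <- function(x) {
  if (length(x) == 0) abort("`x` must be non-empty")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Voronoi-regularized leave-one-out errors
#'
#' The LIV selection score: each point's min-max normalized LOO error plus
#' its min-max normalized Voronoi area, an equally weighted sum in `[0, 2]`.
#' The area term acts as an ad hoc regularizer standing in for the error
#' uncertainty that plain linear interpolation cannot provide -- linear
#' interpolation error tends to grow with distance from the support.
#'
#' @param eps per-point LOO errors.
#' @param areas per-point clipped Voronoi areas.
#' @return Numeric vector in `[0, 2]`.
#' @export
regularized_errors <- function(eps, areas) {
  if (length(eps) != length(areas)) {
    abort("`eps` and `areas` must have equal length")
  }
  normalize_minmax(eps) + normalize_minmax(areas)
}

#' Voronoi-area-weighted mean leave-one-out error
#'
#' The model-accuracy summary of an acquisition run: the mean LOO error with
#' each point weighted by its clipped Voronoi cell area, which corrects for
#' the irregular point distribution adaptive sampling produces.
#'
#' @param eps per-point LOO errors.
#' @param areas per-point Voronoi areas; `sum(areas) > 0`.
#' @return A single number; invariant under uniform rescaling of the areas.
#' @export
mean_weighted_loo <- function(eps, areas) {
  if (length(eps) != length(areas)) {
    abort("`eps` and `areas` must have equal length")
  }
  if (sum(areas) <= 0) abort("`areas` must have positive total")
  sum(areas * eps) / sum(areas)
}

#' Per-point error table driving LIV point selection
#'
#' Convenience wrapper computing, for one iteration of the adaptive loop, the
#' Voronoi partition, the leave-one-out errors, both normalized terms and the
#' regularized LIV error of every sampled point.
#'
#' @param points data frame (columns `x`, `y`) of sampled positions.
#' @param values per-point value vectors (PCA scores or spectra).
#' @param domain rectangle `c(xmin, xmax, ymin, ymax)`.
#' @return A tibble of class `error_table` with columns `point`, `x`, `y`,
#'   `eps_loo`, `area`, `sigma_eps`, `sigma_area`, `eps_liv`.
#' @export
error_table <- function(points, values, domain) {
  points <- as_points_tbl(points)
  part <- voronoi_partition(points, domain)
  eps <- loo_errors_impl(points, values)
  out <- tibble::tibble(
    point = seq_len(nrow(points)),
    x = points$x,
    y = points$y,
    eps_loo = eps,
    area = part$areas,
    sigma_eps = normalize_minmax(eps),
    sigma_area = normalize_minmax(part$areas)
  )
  out$eps_liv <- out$sigma_eps + out$sigma_area
  class(out) <- c("error_table", class(out))
  out
}
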