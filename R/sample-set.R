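#' Construct an ordered set of acquired sample points
#'
#' A sample set is the product of an acquisition run: points in acquisition
#' order, one spectrum per point on a shared wavenumber axis, the domain they
#' were drawn from and (optionally) the RNG seed that produced them.
#'
#' @param points data frame with columns `x`, `y` (micrometres); an `order`
#'   column is added if absent (1..N in row order).
#' @param spectra numeric matrix, one row per point.
#' @param axis wavenumber axis (cm^-1), strictly monotone.
#' @param domain rectangle `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   bounding box of the points (padded so all points are interior).
#' @param seed RNG seed the points were generated with, if any.
#' @return An object of class `sample_set`.
#' @export
sample_set <- function(points, spectra, axis, domain = NULL, seed = NULL) {
  points <- as_points_tbl(points)
  axis <- check_axis(axis)
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  if (nrow(spectra) != nrow(points)) {
    abort("`spectra` must have one row per point")
  }
  if (ncol(spectra) != length(axis)) {
    abort("bad axis: spectra width must match axis length",
          class = "livsampler_error_axis")
  }
  if (is.null(domain)) {
    pad_x <- max(diff(range(points$x)), 1) * 0.01
    pad_y <- max(diff(range(points$y)), 1) * 0.01
    domain <- c(min(points$x) - pad_x, max(points$x) + pad_x,
                min(points$y) - pad_y, max(points$y) + pad_y)
  }
  domain <- as_domain(domain)
  if (!all(in_domain(points$x, points$y, domain))) {
    abort("all points must lie inside the domain",
          class = "livsampler_error_out_of_domain")
  }
  points$order <- seq_len(nrow(points))
  structure(
    list(points = points, spectra = spectra, axis = axis,
         domain = domain, seed = seed),
    class = "sample_set"
  )
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d points, %d wavenumbers (%g..%g cm-1)\n",
              nrow(x$points), length(x$axis), min(x$axis), max(x$axis)))
  invisible(x)
}

#' @export
as_tibble.sample_set <- function(x, ...) {
  ns <- nrow(x$points)
  nf <- length(x$axis)
  tibble::tibble(
    x_um = rep(x$points$x, each = nf),
    y_um = rep(x$points$y, each = nf),
    order = rep(x$points$order, each = nf),
    wavenumber_cm1 = rep(x$axis, times = ns),
    absorbance = as.vector(t(x$spectra))
  )
}

#' Coerce to a sample set
#'
#' @param x object to coerce; for a [spectral_map()] the grid points become
#'   samples in row-major order.
#' @param ... unused.
#' @export
as_sample_set <- function(x, ...) UseMethod("as_sample_set")

#' @export
as_sample_set.sample_set <- function(x, ...) x

#' @export
as_sample_set.spectral_map <- function(x, ...) {
  sample_set(x$positions[c("x", "y")], x$spectra, x$axis, domain = x$domain)
}

#' Write / read a sample set in long-format delimited text
#'
#' Same format as [write_spectral_map()] with an extra `order` column
#' recording acquisition order.
#'
#' @param set a [sample_set()].
#' @param path file path.
#' @return `path` invisibly, or the `sample_set` read back.
#' @export
write_sample_set <- function(set, path) {
  stopifnot(inherits(set, "sample_set"))
  readr::write_csv(fmt_doubles(as_tibble(set)), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_sample_set
#' @export
read_sample_set <- function(path) {
  df <- readr::read_csv(path,
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  num_cols <- c("x_um", "y_um", "wavenumber_cm1", "absorbance")
  df[num_cols] <- lapply(df[num_cols], as.numeric)
  df$order <- as.integer(df$order)
  df <- dplyr::arrange(df, .data$order, .data$wavenumber_cm1)
  axis <- sort(unique(df$wavenumber_cm1))
  pts <- dplyr::distinct(df, .data$order, x = .data$x_um, y = .data$y_um)
  spectra <- matrix(df$absorbance, nrow = nrow(pts), ncol = length(axis),
                    byrow = TRUE)
  sample_set(pts[c("x", "y")], spectra, axis)
}

#' A simulated instrument backed by a ground-truth spectral map
#'
#' Wraps a [spectral_map()] behind the abstract instrument contract used by
#' [run_acquisition()]: `measure(x, y)` returns the spectrum of the spatially
#' closest grid point (the paper-style simulation of live acquisition).
#' Repeated measurement of the same point returns the same spectrum.
#'
#' @param map a [spectral_map()].
#' @return An object of class `instrument` with fields `measure`, `domain`,
#'   `axis`.
#' @export
simulated_instrument <- function(map) {
  stopifnot(inherits(map, "spectral_map"))
  force(map)
  measure <- function(x, y) {
    if (!in_domain(x, y, map$domain)) {
      abort("out of domain", class = "livsampler_error_out_of_domain")
    }
    map$spectra[nearest_grid_index(map, x, y), ]
  }
  structure(list(measure = measure, domain = map$domain, axis = map$axis),
            class = "instrument")
}
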