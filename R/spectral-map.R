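#' Construct a spectral map from grid positions and a spectra matrix
#'
#' A spectral map is the raster "ground truth" of a scanning hyperspectral
#' experiment: a complete rectangular grid of positions (micrometres), one
#' absorbance spectrum per grid point, and a single shared wavenumber axis.
#' Positions are stored in row-major order (increasing y, then increasing x);
#' the map domain is the half-open rectangle extending half a step beyond the
#' outermost grid points, so grid points are cell-representative centres.
#'
#' @param positions data frame with columns `x`, `y` (micrometres) covering a
#'   complete rectangular grid.
#' @param spectra numeric matrix, one row per grid point (in the order of
#'   `positions`), one column per wavenumber.
#' @param axis strictly monotone numeric vector of wavenumbers (cm^-1).
#' @return An object of class `spectral_map`.
#' @examples
#' ax <- seq(1000, 1100, by = 10)
#' pos <- expand.grid(x = 1:4, y = 1:3)
#' sp <- matrix(runif(12 * length(ax)), nrow = 12)
#' m <- spectral_map(pos, sp, ax)
#' m$dims
#' @export
spectral_map <- function(positions, spectra, axis) {
  positions <- as_points_tbl(positions)
  axis <- check_axis(axis)
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  if (nrow(spectra) != nrow(positions)) {
    abort("`spectra` must have one row per position")
  }
  if (ncol(spectra) != length(axis)) {
    abort("bad axis: spectra width must match axis length",
          class = "livsampler_error_axis")
  }
  xs <- sort(unique(positions$x))
  ys <- sort(unique(positions$y))
  n_col <- length(xs)
  n_row <- length(ys)
  if (nrow(positions) != n_col * n_row) {
    abort("ragged grid", class = "livsampler_error_ragged")
  }
  key <- paste(positions$x, positions$y)
  full <- paste(rep(xs, times = n_row), rep(ys, each = n_col))
  if (anyDuplicated(key) || !setequal(key, full)) {
    abort("ragged grid", class = "livsampler_error_ragged")
  }
  # reorder row-major: y ascending, then x ascending
  ord <- order(positions$y, positions$x)
  positions <- positions[ord, , drop = FALSE]
  spectra <- spectra[ord, , drop = FALSE]
  step_x <- if (n_col > 1) min(diff(xs)) else 1
  step_y <- if (n_row > 1) min(diff(ys)) else 1
  positions$row <- rep(seq_len(n_row), each = n_col)
  positions$col <- rep(seq_len(n_col), times = n_row)
  domain <- as_domain(c(min(xs) - step_x / 2, max(xs) + step_x / 2,
                        min(ys) - step_y / 2, max(ys) + step_y / 2))
  structure(
    list(
      positions = positions,
      spectra = spectra,
      axis = axis,
      dims = c(nrow = n_row, ncol = n_col),
      step = c(x = step_x, y = step_y),
      domain = domain
    ),
    class = "spectral_map"
  )
}

check_axis <- function(axis) {
  axis <- as.numeric(axis)
  if (length(axis) < 2 || anyNA(axis) ||
      !(all(diff(axis) > 0) || all(diff(axis) < 0))) {
    abort("bad axis", class = "livsampler_error_axis")
  }
  axis
}

#' Read a spectral map from long-format delimited text
#'
#' The documented interchange format is a delimited text file with header
#' `x_um,y_um,wavenumber_cm1,absorbance`, one row per (position, wavenumber)
#' pair. The grid is inferred from the unique x/y values; an incomplete grid
#' raises a "ragged grid" error, duplicate or inconsistent per-cell wavenumber
#' sets raise "bad axis".
#'
#' @param path file path.
#' @return A [spectral_map()].
#' @export
read_spectral_map <- function(path) {
  # parse numerics via as.numeric (correctly rounded) so values written with
  # 17 significant digits round-trip bit-exactly
  df <- readr::read_csv(path,
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("x_um", "y_um", "wavenumber_cm1", "absorbance")
  if (!all(need %in% names(df))) {
    abort(paste("file must have columns", paste(need, collapse = ", ")))
  }
  df[need] <- lapply(df[need], as.numeric)
  axis <- sort(unique(df$wavenumber_cm1))
  if (length(axis) < 2) abort("bad axis", class = "livsampler_error_axis")
  if (anyDuplicated(df[c("x_um", "y_um", "wavenumber_cm1")])) {
    abort("bad axis", class = "livsampler_error_axis")
  }
  cells <- dplyr::distinct(df, .data$x_um, .data$y_um)
  if (nrow(df) != nrow(cells) * length(axis)) {
    abort("ragged grid", class = "livsampler_error_ragged")
  }
  df <- dplyr::arrange(df, .data$y_um, .data$x_um, .data$wavenumber_cm1)
  spectra <- matrix(df$absorbance, nrow = nrow(cells), ncol = length(axis),
                    byrow = TRUE)
  positions <- dplyr::distinct(df, x = .data$x_um, y = .data$y_um)
  spectral_map(positions, spectra, axis)
}

#' Write a spectral map as long-format delimited text
#'
#' Values round-trip bit-exactly through [read_spectral_map()].
#'
#' @param map a [spectral_map()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_spectral_map <- function(map, path) {
  stopifnot(inherits(map, "spectral_map"))
  readr::write_csv(fmt_doubles(as_tibble(map)), path, progress = FALSE)
  invisible(path)
}

# serialize doubles with 17 significant digits so values round-trip
# bit-exactly through the text format
fmt_doubles <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  })
  df
}

#' @export
as_tibble.spectral_map <- function(x, ...) {
  n0 <- nrow(x$positions)
  nf <- length(x$axis)
  tibble::tibble(
    x_um = rep(x$positions$x, each = nf),
    y_um = rep(x$positions$y, each = nf),
    wavenumber_cm1 = rep(x$axis, times = n0),
    absorbance = as.vector(t(x$spectra))
  )
}

#' @export
print.spectral_map <- function(x, ...) {
  cat(sprintf(
    "<spectral_map> %d x %d grid (%d spectra), %d wavenumbers (%g..%g cm-1)\n",
    x$dims[["nrow"]], x$dims[["ncol"]], nrow(x$positions), length(x$axis),
    min(x$axis), max(x$axis)))
  cat(sprintf("  domain: [%g, %g) x [%g, %g) um, step (%g, %g) um\n",
              x$domain[1], x$domain[2], x$domain[3], x$domain[4],
              x$step[["x"]], x$step[["y"]]))
  invisible(x)
}

#' Spectrum at the grid point nearest to a query position
#'
#' Simulated acquisition serves spectra by nearest-grid lookup: the returned
#' spectrum belongs to the grid point minimizing Euclidean distance to the
#' query, ties broken by lowest row-major grid index.
#'
#' @param map a [spectral_map()].
#' @param point numeric `c(x, y)` in micrometres, inside the map domain.
#' @return A `spectrum` tibble with columns `wavenumber`, `absorbance`.
#' @export
nearest_grid_spectrum <- function(map, point) {
  stopifnot(inherits(map, "spectral_map"))
  point <- as.numeric(point)
  if (length(point) != 2 || anyNA(point)) abort("`point` must be c(x, y)")
  if (!in_domain(point[1], point[2], map$domain)) {
    abort("out of domain", class = "livsampler_error_out_of_domain")
  }
  i <- nearest_grid_index(map, point[1], point[2])
  new_spectrum(map$axis, map$spectra[i, ])
}

# vectorized nearest-grid row index (lowest row-major index on ties)
nearest_grid_index <- function(map, x, y) {
  as.integer(cpp_nearest_index(map$positions$x, map$positions$y, x, y))
}

new_spectrum <- function(axis, intensities) {
  out <- tibble::tibble(wavenumber = as.numeric(axis),
                        absorbance = as.numeric(intensities))
  class(out) <- c("spectrum", class(out))
  out
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %g..%g cm-1\n",
              nrow(x), min(x$wavenumber), max(x$wavenumber)))
  NextMethod()
}
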