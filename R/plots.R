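# ggplot2 autoplot methods for the package's result types

#' @export
autoplot.spectral_map <- function(object, wavenumber = NULL, ...) {
  if (is.null(wavenumber)) {
    z <- rowSums(object$spectra)
    lab <- "total absorbance"
  } else {
    i <- which.min(abs(object$axis - wavenumber))
    z <- object$spectra[, i]
    lab <- sprintf("A(%g cm⁻¹)", object$axis[i])
  }
  df <- dplyr::mutate(object$positions, intensity = z)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}

#' @export
autoplot.spectrum <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$wavenumber, .data$absorbance)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "absorbance (a.u.)")
}

#' @export
autoplot.sample_set <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$x, .data$y, colour = .data$order)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_equal(xlim = object$domain[1:2], ylim = object$domain[3:4]) +
    ggplot2::scale_colour_viridis_c(name = "order") +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}

#' @export
autoplot.voronoi_partition <- function(object, ...) {
  polys <- dplyr::bind_rows(lapply(seq_along(object$polygons), function(i) {
    p <- object$polygons[[i]]
    tibble::tibble(cell = i, x = p[, 1], y = p[, 2],
                   area = object$areas[i])
  }))
  ggplot2::ggplot(polys, ggplot2::aes(.data$x, .data$y, group = .data$cell,
                                      fill = .data$area)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_point(data = object$points, inherit.aes = FALSE,
                        ggplot2::aes(.data$x, .data$y), size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "area (µm²)") +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}

#' @export
autoplot.error_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y,
                                       size = .data$eps_liv,
                                       colour = .data$eps_loo)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c(name = "ε LOO") +
    ggplot2::scale_size_continuous(name = "ε LIV", range = c(0.5, 4)) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}

#' @export
autoplot.acquisition <- function(object, ...) {
  autoplot.sample_set(object$sample_set, ...) +
    ggplot2::ggtitle(sprintf("%s acquisition (%d points)",
                             toupper(object$config$strategy),
                             nrow(object$sample_set$points)))
}

#' @export
autoplot.benchmark_result <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$ratio))
  ggplot2::ggplot(df, ggplot2::aes(.data$ratio)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~ strategy) +
    ggplot2::labs(x = expression(N[s] / N[s]^{UG}), y = "replicates")
}
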