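#' Define a spectral component by its peak list
#'
#' A component standard is a sum of Gaussian and/or Lorentzian peaks on the
#' wavenumber axis, emulating the pure-compound reference spectra used to
#' construct on-target criteria (e.g. a silicone band at 798 cm^-1 or a
#' conjugated C=C band at 1580 cm^-1).
#'
#' @param name component name.
#' @param peaks data frame with columns `center` (cm^-1), `width` (cm^-1),
#'   `height` (a.u.) and optionally `shape` (`"gaussian"` default, or
#'   `"lorentzian"`).
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(name, peaks) {
  peaks <- tibble::as_tibble(peaks)
  if (nrow(peaks) > 0) {
    if (!all(c("center", "width", "height") %in% names(peaks))) {
      abort("`peaks` needs columns center, width, height")
    }
    if (!"shape" %in% names(peaks)) peaks$shape <- "gaussian"
    if (!all(peaks$shape %in% c("gaussian", "lorentzian"))) {
      abort("peak shape must be gaussian or lorentzian")
    }
    if (any(peaks$width <= 0) || any(peaks$height <= 0)) {
      abort("peak widths and heights must be positive")
    }
  }
  structure(list(name = name, peaks = peaks), class = "component_spec")
}

#' Evaluate a component standard on a wavenumber axis
#'
#' @param component a [component_spec()].
#' @param axis wavenumber axis (cm^-1).
#' @return A `spectrum` tibble (non-negative; zero for an empty peak list).
#' @export
component_spectrum <- function(component, axis) {
  stopifnot(inherits(component, "component_spec"))
  axis <- check_axis(axis)
  new_spectrum(axis, peak_profile(component$peaks, axis))
}

peak_profile <- function(peaks, axis) {
  y <- numeric(length(axis))
  for (i in seq_len(nrow(peaks))) {
    d <- axis - peaks$center[i]
    y <- y + if (peaks$shape[i] == "gaussian") {
      peaks$height[i] * exp(-0.5 * (d / peaks$width[i])^2)
    } else {
      peaks$height[i] * peaks$width[i]^2 / (d^2 + peaks$width[i]^2)
    }
  }
  y
}

# anisotropic Gaussian blob concentration field; blobs is a tibble with
# columns x, y, sx, sy, amplitude (centres in um, sds in um, amp >= 0)
blob_field <- function(blobs, x, y) {
  conc <- numeric(length(x))
  for (i in seq_len(nrow(blobs))) {
    conc <- conc + blobs$amplitude[i] *
      exp(-0.5 * (((x - blobs$x[i]) / blobs$sx[i])^2 +
                  ((y - blobs$y[i]) / blobs$sy[i])^2))
  }
  conc
}

#' Generate a synthetic ground-truth spectral map
#'
#' Builds a raster map whose spectrum at each grid point is a non-negative
#' combination of component standards, `Y(x, y) = sum_c conc_c(x, y) * S_c`,
#' plus optional i.i.d. Gaussian noise. Concentration fields are sums of
#' anisotropic Gaussian blobs, the simplest structure with tunable gradients
#' and mixing zones. Bit-identical for a fixed seed.
#'
#' @param components list of [component_spec()] objects.
#' @param fields list (same length) of blob tibbles with columns `x`, `y`,
#'   `sx`, `sy`, `amplitude` -- the concentration field of each component.
#' @param axis wavenumber axis (cm^-1); default 650-4000 at 4 cm^-1, the
#'   instrument's native spectral resolution.
#' @param n_row,n_col grid shape.
#' @param step grid step (um).
#' @param noise_sd additive Gaussian noise standard deviation (a.u.).
#' @param seed RNG seed for the noise (`NULL`: current stream).
#' @param origin lower-left corner of the first cell centre minus half a step.
#' @return A [spectral_map()].
#' @export
generate_map <- function(components, fields, axis = seq(650, 4000, by = 4),
                         n_row = 30, n_col = 30, step = 1.5,
                         noise_sd = 0, seed = NULL, origin = c(0, 0)) {
  stopifnot(length(components) == length(fields), length(components) >= 1)
  axis <- check_axis(axis)
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  xs <- origin[1] + (seq_len(n_col) - 0.5) * step
  ys <- origin[2] + (seq_len(n_row) - 0.5) * step
  gx <- rep(xs, times = n_row)
  gy <- rep(ys, each = n_col)
  conc <- vapply(fields, function(f) blob_field(tibble::as_tibble(f), gx, gy),
                 numeric(length(gx)))
  standards <- t(vapply(components, function(cmp) peak_profile(cmp$peaks, axis),
                        numeric(length(axis))))
  spectra <- conc %*% standards
  if (noise_sd > 0) {
    spectra <- spectra + local_seed(seed, {
      matrix(rnorm(length(spectra), sd = noise_sd),
             nrow = nrow(spectra), ncol = ncol(spectra))
    })
  }
  spectral_map(tibble::tibble(x = gx, y = gy), spectra, axis)
}

#' Preset synthetic maps emulating the two experimental regimes
#'
#' `"two_component"` emulates an abiotic two-component chemical sample: two
#' spatially offset compounds (marker-like with its major band at 1580 cm^-1,
#' grease-like with its silica band at 798 cm^-1) whose concentration blobs
#' overlap in a central mixing zone, on an otherwise empty substrate.
#' `"wormlike"` emulates a whole-organism map: an elongated, gently curved
#' body with three overlapping internal compartments (protein-rich anterior,
#' lipid-rich mid-body, and a hydrated matrix along the whole body),
#' producing smooth multi-compartment spatiochemical gradients.
#'
#' @param preset `"two_component"` or `"wormlike"`.
#' @param n_row,n_col grid shape (default 30 x 30).
#' @param step grid step in um (default 1.5).
#' @param noise_sd additive noise sd (default 0.001 a.u., the absorbance
#'   noise floor of a well-averaged high-brightness measurement).
#' @param seed RNG seed.
#' @param axis wavenumber axis; default 650-4000 at 4 cm^-1.
#' @return A [spectral_map()].
#' @examples
#' m <- synthetic_map("two_component", n_row = 12, n_col = 12,
#'                    axis = seq(650, 4000, 50))
#' @export
synthetic_map <- function(preset = c("two_component", "wormlike"),
                          n_row = 30, n_col = 30, step = 1.5,
                          noise_sd = 0.001, seed = 1L,
                          axis = seq(650, 4000, by = 4)) {
  preset <- match.arg(preset)
  w <- n_col * step
  h <- n_row * step
  if (preset == "two_component") {
    comps <- list(
      component_spec("marker", tibble::tibble(
        center = c(1580, 3050, 1180),
        width = c(18, 22, 15),
        height = c(1.0, 0.35, 0.30)
      )),
      component_spec("grease", tibble::tibble(
        center = c(798, 1262, 2963),
        width = c(12, 10, 18),
        height = c(1.0, 0.45, 0.60)
      ))
    )
    # Two compact deposits on a bare substrate, as in the physical sample:
    # an elongated marker stroke and a roundish grease smear whose tails
    # meet in a mixing zone. The uniform-grid on-target ratio of ~0.19 pins
    # the deposits to roughly a fifth of the mapped area. Lightly applied
    # grease and pooled ink are internally uneven, so each deposit carries
    # fine-scale thickness texture (seeded sub-blobs inside its footprint);
    # without it the deposit interiors would be perfectly interpolable after
    # a handful of samples, which no real smear is.
    marker <- tibble::tibble(
      x = 0.33 * w, y = 0.52 * h,
      sx = 0.045 * w, sy = 0.16 * h,
      amplitude = 0.9
    )
    grease <- tibble::tibble(
      x = 0.62 * w, y = 0.45 * h,
      sx = 0.10 * w, sy = 0.085 * h,
      amplitude = 0.85
    )
    texture <- function(main, n_bump, s_bump, a_bump) {
      tibble::tibble(
        x = rnorm(n_bump, main$x[1], main$sx[1]),
        y = rnorm(n_bump, main$y[1], main$sy[1]),
        sx = s_bump * w, sy = s_bump * w,
        amplitude = a_bump
      )
    }
    return(local_seed(seed, {
      fields <- list(
        dplyr::bind_rows(marker, texture(marker, 6, 0.030, 0.6)),
        dplyr::bind_rows(grease, texture(grease, 8, 0.035, 0.55))
      )
      generate_map(comps, fields, axis = axis, n_row = n_row, n_col = n_col,
                   step = step, noise_sd = noise_sd, seed = NULL)
    }))
  } else {
    # blobs strung along a sinusoidal centreline form the elongated body
    t_body <- seq(0, 1, length.out = 15)
    bx <- (0.10 + 0.80 * t_body) * w
    by <- (0.50 + 0.16 * sin(2.5 * pi * t_body)) * h
    body <- tibble::tibble(
      x = bx, y = by, sx = 0.05 * w, sy = 0.05 * h, amplitude = 0.6
    )
    t_ph <- seq(0.05, 0.22, length.out = 4)
    pharynx <- tibble::tibble(
      x = (0.10 + 0.80 * t_ph) * w,
      y = (0.50 + 0.16 * sin(2.5 * pi * t_ph)) * h,
      sx = 0.035 * w, sy = 0.035 * h, amplitude = 1.0
    )
    t_in <- seq(0.45, 0.85, length.out = 6)
    intestine <- tibble::tibble(
      x = (0.10 + 0.80 * t_in) * w,
      y = (0.50 + 0.16 * sin(2.5 * pi * t_in)) * h,
      sx = 0.045 * w, sy = 0.04 * h, amplitude = 0.9
    )
    comps <- list(
      component_spec("protein", tibble::tibble(
        center = c(1655, 1545, 3290),
        width = c(25, 22, 60),
        height = c(1.0, 0.7, 0.5)
      )),
      component_spec("lipid", tibble::tibble(
        center = c(2925, 2855, 1745),
        width = c(15, 12, 12),
        height = c(1.0, 0.6, 0.5)
      )),
      component_spec("matrix", tibble::tibble(
        center = c(3400, 1640),
        width = c(150, 40),
        height = c(0.6, 0.4)
      ))
    )
    fields <- list(pharynx, intestine, body)
  }
  generate_map(comps, fields, axis = axis, n_row = n_row, n_col = n_col,
               step = step, noise_sd = noise_sd, seed = seed)
}
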