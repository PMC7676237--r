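#' Restrict a spectrum, sample set or map to a wavenumber band
#'
#' Keeps only axis entries with `low <= wavenumber <= high`. Restricting the
#' synchrotron workflow to 900-3700 cm^-1 avoids detector-limit noise at the
#' low end and morphology-driven baseline effects at the high end; the band is
#' fully configurable.
#'
#' @param x a `spectrum`, [sample_set()] or [spectral_map()].
#' @param band numeric `c(low, high)` in cm^-1, `low < high`.
#' @return Object of the same type, with the axis (and intensities) subset.
#' @examples
#' s <- livsampler:::new_spectrum(seq(650, 4000, 50), runif(68))
#' nrow(restrict_band(s, c(900, 3700)))
#' @export
restrict_band <- function(x, band) UseMethod("restrict_band")

#' @export
restrict_band.spectrum <- function(x, band) {
  idx <- band_indices(x$wavenumber, band)
  if (length(idx) == 0) abort("empty band", class = "livsampler_error_band")
  new_spectrum(x$wavenumber[idx], x$absorbance[idx])
}

#' @export
restrict_band.sample_set <- function(x, band) {
  idx <- band_indices(x$axis, band)
  if (length(idx) == 0) abort("empty band", class = "livsampler_error_band")
  x$axis <- x$axis[idx]
  x$spectra <- x$spectra[, idx, drop = FALSE]
  x
}

#' @export
restrict_band.spectral_map <- function(x, band) {
  idx <- band_indices(x$axis, band)
  if (length(idx) == 0) abort("empty band", class = "livsampler_error_band")
  x$axis <- x$axis[idx]
  x$spectra <- x$spectra[, idx, drop = FALSE]
  x
}

# lower convex hull (Andrew chain) of (axis, y); returns vertex indices.
# The rubber-band baseline is this envelope linearly interpolated.
lower_hull_indices <- function(x, y) {
  n <- length(x)
  keep <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      a <- keep[k - 1L]
      b <- keep[k]
      # pop b unless (a, b, i) turns left (b strictly below chord a-i)
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross <= 0) k <- k - 1L else break
    }
    k <- k + 1L
    keep[k] <- i
  }
  keep[seq_len(k)]
}

rubberband_one <- function(axis, y) {
  h <- lower_hull_indices(axis, y)
  baseline <- approx(axis[h], y[h], xout = axis, rule = 2)$y
  y - baseline
}

#' Rubber-band baseline correction
#'
#' Subtracts the lower convex-hull envelope of the (wavenumber, absorbance)
#' points, linearly interpolated between hull vertices. The corrected spectrum
#' is non-negative up to numeric tolerance and is exactly zero at both
#' endpoints; the operation is idempotent on already-corrected spectra.
#'
#' @param x a `spectrum` or [sample_set()] (corrected spectrum-wise).
#' @return Object of the same type.
#' @export
rubberband_baseline <- function(x) UseMethod("rubberband_baseline")

#' @export
rubberband_baseline.spectrum <- function(x) {
  if (nrow(x) < 2) abort("need at least 2 spectral points")
  new_spectrum(x$wavenumber, rubberband_one(x$wavenumber, x$absorbance))
}

#' @export
rubberband_baseline.sample_set <- function(x) {
  x$spectra <- rubberband_rows(x$spectra, x$axis)
  x
}

rubberband_rows <- function(mat, axis) {
  t(apply(mat, 1, function(r) rubberband_one(axis, r)))
}

#' Reduce a sample set to principal-component scores
#'
#' Mean-centred PCA over the acquired spectra; the adaptive loop operates on
#' the first few score dimensions (five by default) instead of the full
#' spectral vector, which keeps the leave-one-out error calculation cheap
#' while preserving most spectral variance. Scores are raw (not whitened), so
#' the L2 leave-one-out error weights components by their variance. The number
#' of components actually fitted is `min(n_components, N_s - 1, N_f)`. Signs
#' follow a deterministic convention: the largest-magnitude loading element of
#' each component is positive.
#'
#' @param set a [sample_set()].
#' @param n_components requested number of components (default 5).
#' @return An object of class `reduced_sample_set` with fields `points`,
#'   `scores` (N_s x n_c), `loadings` (N_f x n_c), `center`,
#'   `explained_variance` (fractions, non-increasing) and `axis`.
#' @export
pca_reduce <- function(set, n_components = 5) {
  stopifnot(inherits(set, "sample_set"))
  check_scalar_number(n_components, "n_components", min = 1)
  n_s <- nrow(set$points)
  if (n_s < 2) abort("insufficient samples", class = "livsampler_error_pca")
  red <- pca_scores(set$spectra, n_components)
  structure(
    c(list(points = set$points, axis = set$axis, domain = set$domain), red),
    class = "reduced_sample_set"
  )
}

# core PCA used both by pca_reduce() and the acquisition loop
pca_scores <- function(mat, n_components) {
  n_s <- nrow(mat)
  n_f <- ncol(mat)
  n_c <- min(n_components, n_s - 1, n_f)
  p <- prcomp(mat, center = TRUE, scale. = FALSE)
  total_var <- sum(p$sdev^2)
  n_c <- min(n_c, ncol(p$rotation))
  scores <- p$x[, seq_len(n_c), drop = FALSE]
  loadings <- p$rotation[, seq_len(n_c), drop = FALSE]
  for (j in seq_len(n_c)) {
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- if (total_var > 0) p$sdev[seq_len(n_c)]^2 / total_var else rep(0, n_c)
  list(scores = scores, loadings = loadings, center = p$center,
       explained_variance = ev, n_components = n_c)
}

#' @export
print.reduced_sample_set <- function(x, ...) {
  cat(sprintf("<reduced_sample_set> %d points, %d components (EV %s)\n",
              nrow(x$points), x$n_components,
              paste(signif(x$explained_variance, 3), collapse = ", ")))
  invisible(x)
}

#' Signal-to-noise filtering of spectra
#'
#' Removes spectra close to the instrument detection limit before deriving
#' on-target criteria. The SNR of a spectrum is the mean absolute intensity
#' inside `signal_band` divided by the standard deviation inside `quiet_band`
#' (a band expected to carry no analyte signal); spectra with
#' `SNR >= snr_min` are kept, in their original order. A zero quiet-band
#' standard deviation yields infinite SNR (kept).
#'
#' @param set a [sample_set()].
#' @param signal_band,quiet_band disjoint bands `c(low, high)` in cm^-1.
#' @param snr_min minimum SNR to keep a spectrum.
#' @return The filtered [sample_set()].
#' @export
noise_filter <- function(set, signal_band, quiet_band, snr_min) {
  stopifnot(inherits(set, "sample_set"))
  signal_band <- as_band(signal_band)
  quiet_band <- as_band(quiet_band)
  check_scalar_number(snr_min, "snr_min")
  if (signal_band[1] <= quiet_band[2] && quiet_band[1] <= signal_band[2]) {
    abort("signal and quiet bands must be disjoint",
          class = "livsampler_error_band")
  }
  snr <- spectrum_snr(set$spectra, set$axis, signal_band, quiet_band)
  keep <- which(snr >= snr_min)
  subset_sample_set(set, keep)
}

spectrum_snr <- function(mat, axis, signal_band, quiet_band) {
  si <- band_indices(axis, signal_band)
  qi <- band_indices(axis, quiet_band)
  if (length(si) == 0 || length(qi) == 0) {
    abort("empty band", class = "livsampler_error_band")
  }
  signal <- rowMeans(abs(mat[, si, drop = FALSE]))
  noise <- apply(mat[, qi, drop = FALSE], 1, sd)
  noise[is.na(noise)] <- 0
  ifelse(noise == 0, Inf, signal / noise)
}

subset_sample_set <- function(set, idx) {
  set$points <- set$points[idx, , drop = FALSE]
  set$points$order <- seq_len(length(idx))
  set$spectra <- set$spectra[idx, , drop = FALSE]
  set
}
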