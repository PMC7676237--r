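# internal helpers shared across modules

# run code under a temporary RNG seed, restoring the caller's RNG state;
# seed = NULL means "use the current RNG stream"
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# domain rectangles are c(xmin, xmax, ymin, ymax) in micrometres,
# half-open: [xmin, xmax) x [ymin, ymax)
as_domain <- function(domain) {
  domain <- as.numeric(domain)
  if (length(domain) != 4 || anyNA(domain) ||
      domain[1] >= domain[2] || domain[3] >= domain[4]) {
    abort("`domain` must be c(xmin, xmax, ymin, ymax) with xmin < xmax, ymin < ymax",
          class = "livsampler_error_domain")
  }
  names(domain) <- c("xmin", "xmax", "ymin", "ymax")
  domain
}

in_domain <- function(x, y, domain) {
  x >= domain[1] & x < domain[2] & y >= domain[3] & y < domain[4]
}

domain_area <- function(domain) {
  (domain[[2]] - domain[[1]]) * (domain[[4]] - domain[[3]])
}

# accept a two-column matrix/data frame (x, y) or a length-2 numeric
as_points_tbl <- function(points) {
  if (is.numeric(points) && is.null(dim(points)) && length(points) == 2) {
    return(tibble::tibble(x = points[[1]], y = points[[2]]))
  }
  if (is.matrix(points)) {
    return(tibble::tibble(x = points[, 1], y = points[, 2]))
  }
  if (is.data.frame(points)) {
    if (!all(c("x", "y") %in% names(points))) {
      abort("`points` needs columns `x` and `y`")
    }
    return(tibble::tibble(x = as.numeric(points$x), y = as.numeric(points$y)))
  }
  abort("`points` must be a data frame, two-column matrix, or length-2 numeric")
}

as_values_matrix <- function(values, n) {
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != n) {
    abort("`values` must have one row per point")
  }
  values
}

# spectral band c(low, high) in wavenumbers
as_band <- function(band) {
  band <- as.numeric(band)
  if (length(band) != 2 || anyNA(band) || band[1] >= band[2]) {
    abort("a band must be c(low, high) with low < high",
          class = "livsampler_error_band")
  }
  band
}

band_indices <- function(axis, band) {
  band <- as_band(band)
  which(axis >= band[1] & axis <= band[2])
}

check_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s", name, format(min)))
  }
  invisible(x)
}
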