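#' Binned hyperspectral datacube for one polarity
#'
#' Per-pixel, per-bin ion counts stored as a sparse `npixels x n_bins`
#' matrix (ToF-SIMS spectra are overwhelmingly empty at 0.05-Da binning).
#' Pixels are row-major with origin at the top-left: pixel index
#' `(row - 1) * nx + col` for 1-based `row`/`col`.
#'
#' @param counts Sparse or dense numeric matrix, `nx*ny` rows (pixels) by
#'   `axis$n_bins` columns; all entries non-negative.
#' @param nx,ny Image width and height in pixels.
#' @param axis A [mass_axis()].
#' @param polarity `+1` (positive mode) or `-1` (negative mode).
#' @param metadata Optional named list (condition label, replicate id, ...).
#' @return A `spectral_image`.
#' @export
spectral_image <- function(counts, nx, ny, axis, polarity,
                           metadata = list()) {
  counts <- methods::as(counts, "CsparseMatrix")
  stopifnot(nrow(counts) == nx * ny, ncol(counts) == axis$n_bins,
            polarity %in% c(-1, 1))
  if (any(counts@x < 0)) stop("negative intensities in datacube")
  structure(list(counts = counts, nx = as.integer(nx), ny = as.integer(ny),
                 axis = axis, polarity = as.integer(polarity),
                 metadata = metadata),
            class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  cat(sprintf("<spectral_image> %dx%d px, %s mode, %d bins, %.0f total counts\n",
              x$nx, x$ny, if (x$polarity > 0) "positive" else "negative",
              x$axis$n_bins, sum(x$counts)))
  invisible(x)
}

# Pixel index helpers (row-major, origin top-left, 1-based rows/cols).
pixel_index <- function(nx, row, col) (row - 1L) * nx + col

#' Bin a list of ion events into a datacube
#'
#' Events are (pixel, m/z, intensity) triples; intensities are summed into
#' the half-open bin containing each m/z (counts, not averages). Events
#' outside the axis range are dropped, tallied, and reported with a warning.
#'
#' @param events Data frame with columns `pixel` (1-based row-major index),
#'   `mz`, `intensity` (non-negative).
#' @param axis A [mass_axis()].
#' @param nx,ny Image geometry.
#' @param polarity,metadata Passed to [spectral_image()].
#' @return A `spectral_image`; attribute `"n_dropped"` counts out-of-range
#'   events.
#' @export
bin_events <- function(events, axis, nx, ny, polarity = 1L,
                       metadata = list()) {
  stopifnot(all(c("pixel", "mz", "intensity") %in% names(events)))
  if (any(events$intensity < 0)) stop("negative event intensities")
  bins <- bin_of(axis, events$mz)
  drop <- is.na(bins)
  if (any(drop))
    warning(sum(drop), " event(s) outside the mass axis were dropped")
  keep <- !drop
  counts <- Matrix::sparseMatrix(
    i = events$pixel[keep], j = bins[keep], x = events$intensity[keep],
    dims = c(nx * ny, axis$n_bins)
  )
  img <- spectral_image(counts, nx, ny, axis, polarity, metadata)
  attr(img, "n_dropped") <- sum(drop)
  img
}

#' Ion image: per-pixel summed counts in an m/z window
#'
#' Sums counts over all bins intersecting `[center - half_width,
#' center + half_width)` and returns them as an `ny x nx` matrix.
#'
#' @param image A `spectral_image`.
#' @param center_mz Window center in Da.
#' @param half_width Window half-width in Da; default one bin width.
#' @return An `ion_image`: matrix (rows = image rows) with attributes
#'   `center_mz`, `half_width`, `bins`.
#' @export
#' @examples
#' # ion_image(img, 184.07)   # PC-headgroup marker image
ion_image <- function(image, center_mz, half_width = image$axis$bin_width) {
  ax <- image$axis
  lo <- center_mz - half_width
  hi <- center_mz + half_width
  bins <- which(bin_centers(ax) + ax$bin_width / 2 > lo &
                bin_centers(ax) - ax$bin_width / 2 < hi)
  if (!length(bins)) stop("m/z window does not overlap the mass axis")
  v <- Matrix::rowSums(image$counts[, bins, drop = FALSE])
  m <- matrix(v, nrow = image$ny, ncol = image$nx, byrow = TRUE)
  structure(m, class = c("ion_image", "matrix"),
            center_mz = center_mz, half_width = half_width, bins = bins)
}

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf("<ion_image> %dx%d px at m/z %.3f +/- %.3f, total %.0f\n",
              ncol(x), nrow(x), attr(x, "center_mz"), attr(x, "half_width"),
              sum(x)))
  invisible(x)
}

# Elementwise sum of ion images (additivity over disjoint windows).
#' @export
`+.ion_image` <- function(e1, e2) {
  stopifnot(all(dim(e1) == dim(e2)))
  structure(unclass(e1) + unclass(e2), class = c("ion_image", "matrix"),
            center_mz = NA_real_, half_width = NA_real_,
            bins = union(attr(e1, "bins"), attr(e2, "bins")))
}
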