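#' Uniformly binned m/z axis
#'
#' The shared mass grid of all binned spectra: half-open bins
#' `[start + i*w, start + (i+1)*w)` so every m/z in `[start, stop)` belongs
#' to exactly one bin and a value on a boundary belongs to the upper bin.
#' Defaults match the acquisition mass range (100-1000 Da) binned to
#' 0.05 Da, i.e. 18000 bins (~62 ppm bin width at m/z 800).
#'
#' @param start,stop Axis range in Da.
#' @param bin_width Bin width in Da; `(stop - start) / bin_width` must be
#'   integral.
#' @return A `mass_axis` object with `start`, `stop`, `bin_width`, `n_bins`.
#' @export
#' @examples
#' ax <- mass_axis()
#' bin_of(ax, 184.07)
mass_axis <- function(start = 100, stop = 1000, bin_width = 0.05) {
  stopifnot(stop > start, bin_width > 0)
  n <- (stop - start) / bin_width
  if (abs(n - round(n)) > 1e-9)
    stop("(stop - start) must be an integer multiple of bin_width")
  structure(list(start = start, stop = stop, bin_width = bin_width,
                 n_bins = as.integer(round(n))),
            class = "mass_axis")
}

#' @export
print.mass_axis <- function(x, ...) {
  cat(sprintf("<mass_axis> %g-%g Da, %g Da bins (%d bins)\n",
              x$start, x$stop, x$bin_width, x$n_bins))
  invisible(x)
}

#' Bin index of an m/z value (1-based)
#'
#' @param axis A `mass_axis`.
#' @param mz Numeric m/z values.
#' @return Integer bin indices in `1..n_bins`; `NA` for out-of-range values
#'   (including `mz == stop`, which falls outside the half-open last bin).
#' @export
bin_of <- function(axis, mz) {
  # small relative nudge so bin boundaries robustly fall in the upper bin
  # despite floating-point representation of mz - start
  u <- (mz - axis$start) / axis$bin_width
  i <- floor(u + 1e-9) + 1
  i[mz < axis$start | mz >= axis$stop] <- NA
  as.integer(i)
}

#' Bin centers of the axis
#' @param axis A `mass_axis`.
#' @param bins Bin indices (default all).
#' @return Numeric vector of bin-center m/z values.
#' @export
bin_centers <- function(axis, bins = seq_len(axis$n_bins)) {
  axis$start + (bins - 0.5) * axis$bin_width
}

axes_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}
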