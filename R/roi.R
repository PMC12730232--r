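#' Default marker-ion windows for cell-area selection
#'
#' Cells are located through lipid marker ions: the phosphocholine headgroup
#' fragment at m/z 184.07 in positive mode, and the palmitic/stearic acid
#' carboxylates at m/z 255.23 and 283.26 in negative mode.
#'
#' @param polarity `+1` or `-1`.
#' @return Numeric vector of marker window centers (Da).
#' @export
default_marker_mzs <- function(polarity) {
  if (polarity > 0) 184.07 else c(255.23, 283.26)
}

#' Marker-ion image of a datacube
#'
#' Sum of [ion_image()] windows at the polarity's marker m/z values.
#'
#' @param image A `spectral_image`.
#' @param marker_mzs Window centers; defaults per polarity.
#' @param half_width Window half-width (Da).
#' @return An `ion_image`.
#' @export
marker_image <- function(image, marker_mzs = default_marker_mzs(image$polarity),
                         half_width = image$axis$bin_width) {
  imgs <- lapply(marker_mzs, function(m) ion_image(image, m, half_width))
  Reduce(`+`, imgs)
}

#' Otsu threshold of non-negative image values
#'
#' Histogram-based between-class variance maximization; deterministic for a
#' fixed bin count. Used to separate cell footprints from the substrate
#' background in marker images.
#'
#' @param values Numeric vector or matrix of non-negative intensities.
#' @param n_breaks Number of histogram bins.
#' @return Threshold value; pixels strictly above it are foreground.
#' @export
threshold_otsu <- function(values, n_breaks = 256L) {
  v <- as.numeric(values)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])  # flat image: nothing above threshold
  breaks <- seq(rng[1], rng[2], length.out = n_breaks + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                nbins = n_breaks)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  # the criterion plateaus across empty histogram gaps; take the plateau
  # midpoint so the threshold sits between the modes
  peak <- which(between >= max(between) - 1e-12)
  mean(mids[peak])
}

# 4-connected component labelling of a logical matrix (iterative flood fill;
# deterministic: labels assigned in row-major scan order).
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  labels <- matrix(0L, ny, nx)
  current <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    stack <- start
    labels[start] <- current
    while (length(stack)) {
      idx <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((idx - 1L) %% ny) + 1L
      c <- ((idx - 1L) %/% ny) + 1L
      for (nb in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (nb[1] < 1L || nb[1] > ny || nb[2] < 1L || nb[2] > nx) next
        j <- (nb[2] - 1L) * ny + nb[1]
        if (mask[j] && labels[j] == 0L) {
          labels[j] <- current
          stack <- c(stack, j)
        }
      }
    }
  }
  labels
}

#' Segment cell ROIs from a marker image
#'
#' Thresholds the marker image (Otsu by default, or a fixed fraction of the
#' maximum), labels 4-connected components, discards components smaller than
#' `min_roi_pixels`, and orders the ROIs by their top-most, then left-most
#' pixel so runs are reproducible.
#'
#' @param marker An `ion_image` (or numeric matrix) of marker intensities.
#' @param method `"otsu"` or `"fraction"`.
#' @param min_roi_pixels Minimum component size in pixels (default 20, about
#'   the smallest credible cell footprint at 128 x 128 pixels over 600 um).
#' @param fraction Threshold as a fraction of the maximum when
#'   `method = "fraction"`.
#' @return List of `roi_mask` objects (logical `ny x nx` matrices with
#'   `roi_id` and `pixel_count` attributes); empty list for an all-zero
#'   marker.
#' @export
segment_rois <- function(marker, method = c("otsu", "fraction"),
                         min_roi_pixels = 20L, fraction = 0.5) {
  method <- match.arg(method)
  m <- unclass(marker)
  if (all(m == 0)) return(list())
  thr <- switch(method,
    otsu = threshold_otsu(m),
    fraction = fraction * max(m)
  )
  fg <- m > thr
  if (!any(fg)) return(list())
  labels <- label_components(fg)
  ids <- setdiff(unique(as.integer(labels)), 0L)
  rois <- list()
  for (id in ids) {
    mask <- labels == id
    if (sum(mask) < min_roi_pixels) next
    rois[[length(rois) + 1L]] <- mask
  }
  if (!length(rois)) return(list())
  # order by (top-most, then left-most) pixel, row-major
  key <- vapply(rois, function(mask) {
    hit <- which(t(mask))[1]  # row-major scan
    hit
  }, numeric(1))
  rois <- rois[order(key)]
  lapply(seq_along(rois), function(i) {
    structure(rois[[i]], class = c("roi_mask", "matrix"),
              roi_id = i, pixel_count = sum(rois[[i]]))
  })
}

#' Summed spectrum of one ROI
#'
#' Per-bin sum of counts over the masked pixels: the cell-area spectrum that
#' is the statistical unit of all downstream comparisons.
#'
#' @param image A `spectral_image`.
#' @param mask A logical `ny x nx` matrix (`roi_mask`).
#' @param condition,replicate Optional labels stored on the result.
#' @return A `roi_spectrum` with fields `raw` (numeric, per bin),
#'   `normalized` (`NULL` until [tic_normalize()]), `removed_bins`,
#'   `axis`, `polarity`.
#' @export
roi_spectrum <- function(image, mask, condition = NA_character_,
                         replicate = NA_integer_) {
  stopifnot(nrow(mask) == image$ny, ncol(mask) == image$nx)
  if (!any(mask)) stop("empty ROI mask")
  # mask is ny x nx (row, col); pixels are row-major
  px <- which(t(mask))
  raw <- Matrix::colSums(image$counts[px, , drop = FALSE])
  structure(list(
    roi_id = attr(mask, "roi_id"),
    condition = condition, replicate = replicate,
    polarity = image$polarity, axis = image$axis,
    raw = as.numeric(raw), normalized = NULL,
    removed_bins = integer(0)
  ), class = "roi_spectrum")
}

#' @export
print.roi_spectrum <- function(x, ...) {
  cat(sprintf("<roi_spectrum> roi %s, %s mode, total %.0f counts%s\n",
              format(x$roi_id), if (x$polarity > 0) "positive" else "negative",
              sum(x$raw), if (!is.null(x$normalized)) ", normalized" else ""))
  invisible(x)
}

#' Default substrate interference peaks
#'
#' Major secondary ions of the indium tin oxide (ITO) substrate to be
#' removed before normalization. The exact interference list is
#' instrument- and substrate-batch-specific; these defaults (indium and two
#' cluster/oxide ions per polarity) are documented stand-ins that match the
#' synthetic generator.
#'
#' @param polarity `+1` or `-1`.
#' @return Numeric vector of interference m/z values.
#' @export
default_interference_mzs <- function(polarity) {
  if (polarity > 0) c(114.904, 229.808, 245.803)
  else c(130.899, 146.894, 261.803)
}

#' Zero out substrate interference bins
#'
#' The bin containing each listed interference m/z is set to zero and
#' recorded in `removed_bins`. Idempotent; applied before TIC
#' normalization.
#'
#' @param spectrum A `roi_spectrum`.
#' @param interference_mzs Substrate peak list; defaults per polarity.
#' @return The spectrum with interference bins zeroed.
#' @export
remove_interference <- function(spectrum,
                                interference_mzs =
                                  default_interference_mzs(spectrum$polarity)) {
  bins <- bin_of(spectrum$axis, interference_mzs)
  bins <- bins[!is.na(bins)]
  spectrum$raw[bins] <- 0
  if (!is.null(spectrum$normalized)) spectrum$normalized[bins] <- 0
  spectrum$removed_bins <- sort(union(spectrum$removed_bins, bins))
  spectrum
}

#' Total-ion-current normalization
#'
#' Divides every retained bin by the total retained intensity so the
#' spectrum sums to one; scale-invariant. Interference bins removed earlier
#' stay zero.
#'
#' @param spectrum A `roi_spectrum` with positive total intensity.
#' @return The spectrum with `normalized` filled in.
#' @export
tic_normalize <- function(spectrum) {
  tot <- sum(spectrum$raw)
  if (tot <= 0) stop("cannot TIC-normalize a spectrum with zero total intensity")
  spectrum$normalized <- spectrum$raw / tot
  spectrum
}

#' Extract, clean and normalize all ROI spectra of a datacube
#'
#' Convenience pipeline: marker image, segmentation, per-ROI spectra,
#' interference removal, then TIC normalization (in that fixed order).
#'
#' @param image A `spectral_image`.
#' @param masks Optional list of ROI masks to bypass segmentation (e.g.
#'   manually drawn regions).
#' @param interference_mzs Substrate peak list; defaults per polarity.
#' @param condition,replicate Labels stored on each spectrum.
#' @param ... Passed to [segment_rois()].
#' @return List of normalized `roi_spectrum` objects.
#' @export
extract_roi_spectra <- function(image, masks = NULL,
                                interference_mzs =
                                  default_interference_mzs(image$polarity),
                                condition = NA_character_,
                                replicate = NA_integer_, ...) {
  if (is.null(masks)) masks <- segment_rois(marker_image(image), ...)
  lapply(masks, function(m) {
    s <- roi_spectrum(image, m, condition = condition, replicate = replicate)
    s <- remove_interference(s, interference_mzs)
    tic_normalize(s)
  })
}
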