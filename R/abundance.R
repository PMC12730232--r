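#' Mean spectrum (with SEM) over ROI spectra
#'
#' @param spectra List of normalized `roi_spectrum` objects sharing an axis.
#' @param what `"normalized"` (default) or `"raw"`.
#' @return List with `mean`, `sem` (numeric per bin), `axis`, `polarity`,
#'   `n`.
#' @export
mean_spectrum <- function(spectra, what = c("normalized", "raw")) {
  what <- match.arg(what)
  stopifnot(length(spectra) >= 1)
  ax <- spectra[[1]]$axis
  for (s in spectra)
    if (!axes_equal(s$axis, ax)) stop("ROI spectra do not share a mass axis")
  mat <- do.call(rbind, lapply(spectra, function(s) {
    v <- s[[what]]
    if (is.null(v)) stop("spectra must be normalized first (tic_normalize)")
    v
  }))
  n <- nrow(mat)
  mu <- colMeans(mat)
  sem <- if (n > 1) apply(mat, 2, stats::sd) / sqrt(n) else rep(0, ncol(mat))
  list(mean = mu, sem = sem, axis = ax, polarity = spectra[[1]]$polarity,
       n = n)
}

#' Pick peaks on a mean spectrum
#'
#' Strict local maxima of the binned mean spectrum above an intensity floor
#' (`min_rel_intensity` times the spectrum maximum) and above a prominence
#' floor (`min_prominence_mad` times the median absolute deviation of the
#' nonzero bins). Deterministic; equal-intensity neighbours are not maxima
#' (a flat spectrum yields no peaks). Returned in ascending bin order.
#'
#' @param ms A mean spectrum from [mean_spectrum()], or a bare numeric
#'   vector (then `axis` must be supplied).
#' @param min_rel_intensity Intensity floor relative to the maximum.
#' @param min_prominence_mad Prominence floor in MAD units.
#' @param axis Mass axis when `ms` is a bare vector.
#' @return Data frame `bin`, `mz`, `intensity` (one row per peak).
#' @export
pick_peaks <- function(ms, min_rel_intensity = 1e-4,
                       min_prominence_mad = 2, axis = NULL) {
  if (is.numeric(ms)) ms <- list(mean = ms, axis = axis)
  v <- ms$mean
  if (is.null(ms$axis)) stop("mass axis required")
  if (all(v == 0)) return(data.frame(bin = integer(0), mz = numeric(0),
                                     intensity = numeric(0)))
  n <- length(v)
  left <- c(Inf, v[-n])   # sentinel: edge bins need a strictly lower inner neighbour
  right <- c(v[-1], Inf)
  is_max <- v > left & v > right
  is_max[1] <- v[1] > v[2]
  is_max[n] <- v[n] > v[n - 1]
  floor_int <- min_rel_intensity * max(v)
  nz <- v[v > 0]
  prom <- min_prominence_mad * stats::mad(nz, center = stats::median(nz))
  keep <- which(is_max & v >= floor_int & v >= prom)
  data.frame(bin = keep, mz = bin_centers(ms$axis, keep), intensity = v[keep])
}

#' Top-n peak table by mean intensity
#'
#' Ranks peaks by descending mean intensity (ties broken toward lower m/z)
#' and keeps the `n` most abundant; if fewer peaks exist, all are returned
#' with a warning. Default n = 45, the per-polarity count used for the
#' abundance profile (45 peaks per ion mode, 90 in total).
#'
#' @param peaks Peak data frame from [pick_peaks()].
#' @param ms Mean spectrum (provides SEM and polarity), optional.
#' @param n Number of peaks to keep.
#' @return A `peak_table` data frame: `rank`, `bin`, `mz`, `mean_intensity`,
#'   `sem`, `polarity`.
#' @export
top_n_peaks <- function(peaks, ms = NULL, n = 45L) {
  if (nrow(peaks) < n) {
    warning("only ", nrow(peaks), " peaks available; requested ", n)
    n <- nrow(peaks)
  }
  ord <- order(-peaks$intensity, peaks$mz, method = "radix")
  sel <- peaks[ord[seq_len(n)], , drop = FALSE]
  out <- data.frame(
    rank = seq_len(n), bin = sel$bin, mz = sel$mz,
    mean_intensity = sel$intensity,
    sem = if (!is.null(ms)) ms$sem[sel$bin] else NA_real_,
    polarity = if (!is.null(ms) && !is.null(ms$polarity)) ms$polarity
               else NA_integer_
  )
  rownames(out) <- NULL
  class(out) <- c("peak_table", class(out))
  out
}

#' Lipid-class summary of an annotated peak table
#'
#' Counts the best assignment's lipid class for every entry of the combined
#' (both-polarity) top-peak table and reports fractions of the total. Peaks
#' without a candidate are counted as `"unassigned"`. Entries are top-peak
#' entries, not unique species: a lipid detected as several ionization
#' forms counts once per form, matching how abundance profiles are usually
#' summarized. Set `unique_species = TRUE` to collapse adduct duplicates.
#'
#' @param peak_table A `peak_table` (or combined rbind of both polarities).
#' @param assignments List from [annotate()] aligned with the rows.
#' @param unique_species Collapse multiple ion forms of one species.
#' @return A `class_summary` data frame: `class`, `count`, `fraction`
#'   (fractions over assigned + unassigned entries sum to 1).
#' @export
class_summary <- function(peak_table, assignments,
                          unique_species = FALSE) {
  stopifnot(nrow(peak_table) == length(assignments))
  cls <- vapply(assignments, function(a)
    if (a$assigned) a$candidates$class[1] else "unassigned", character(1))
  nm <- vapply(assignments, function(a)
    if (a$assigned) a$candidates$name[1] else NA_character_, character(1))
  if (unique_species) {
    keep <- !duplicated(ifelse(is.na(nm), paste0("unassigned@",
                                                 peak_table$mz), nm))
    cls <- cls[keep]
  }
  tab <- table(cls)
  out <- data.frame(class = names(tab), count = as.integer(tab),
                    fraction = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$class), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("class_summary", class(out))
  out
}
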