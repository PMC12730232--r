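#' Read a lipid species table and expand it to an ion library
#'
#' The species TSV has columns `name` (shorthand), `ions` (comma-separated
#' ion-form suffixes such as `"+H,+Na,+K"`) and optional
#' `explicit_formula` for rule-less classes; comment lines start with `#`.
#'
#' @param path TSV path.
#' @return An `ion_library` (see [build_ion_library()]).
#' @export
read_lipid_library <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!"explicit_formula" %in% names(tab)) tab$explicit_formula <- ""
  tab$explicit_formula[is.na(tab$explicit_formula)] <- ""
  build_ion_library(tab)
}

#' Write an ion library as TSV (computed formula and m/z per ion)
#'
#' @param lib An `ion_library`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ion_library <- function(lib, path) {
  out <- lib[, setdiff(names(lib), "ion")]
  write_result_tsv(out, path, params = list(n_ions = nrow(lib)))
}

#' Read/write ROI masks as TSV pixel lists or PNG
#'
#' The TSV form lists 1-based `row`/`col` pixel coordinates (origin
#' top-left); the PNG form is a 0/255 grayscale image. Masks written by
#' either route can be fed back to [roi_spectrum()] or
#' [extract_roi_spectra()] in place of automatic segmentation.
#'
#' @param mask Logical `ny x nx` matrix.
#' @param path Output path; format chosen by extension (`.tsv` or `.png`).
#' @return `path` (write) or the logical mask (read).
#' @export
write_roi_mask <- function(mask, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required for PNG masks")
    png::writePNG(ifelse(mask, 1, 0), path)
  } else {
    idx <- which(mask, arr.ind = TRUE)
    utils::write.table(
      data.frame(row = idx[, 1], col = idx[, 2],
                 ny = nrow(mask), nx = ncol(mask)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_roi_mask
#' @param ny,nx Geometry for TSV masks lacking embedded dimensions.
#' @export
read_roi_mask <- function(path, ny = NULL, nx = NULL) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required for PNG masks")
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(img > 0.5)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(ny)) ny <- tab$ny[1]
  if (is.null(nx)) nx <- tab$nx[1]
  m <- matrix(FALSE, ny, nx)
  m[cbind(tab$row, tab$col)] <- TRUE
  m
}

#' Read a one-column interference m/z list (TSV, `#` comments allowed)
#'
#' @param path File with one m/z per line.
#' @return Numeric vector of interference m/z values.
#' @export
read_interference_list <- function(path) {
  v <- utils::read.delim(path, comment.char = "#", header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  as.numeric(v)
}

#' Export a per-ROI spectrum as TSV (bin center, raw, normalized)
#'
#' Zero bins are omitted to keep files small; `removed_bins` are listed in
#' the header.
#'
#' @param spectrum A `roi_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_spectrum_tsv <- function(spectrum, path) {
  keep <- which(spectrum$raw != 0)
  df <- data.frame(
    mz = bin_centers(spectrum$axis, keep),
    raw = spectrum$raw[keep],
    normalized = if (!is.null(spectrum$normalized))
      spectrum$normalized[keep] else NA_real_)
  write_result_tsv(df, path,
                   params = list(roi_id = spectrum$roi_id,
                                 removed_bins = spectrum$removed_bins))
  invisible(path)
}
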