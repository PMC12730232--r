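#' Abundance-profile pipeline
#'
#' The first deliverable of the analysis: from normalized per-cell spectra
#' of both polarities to the ranked top-45-per-polarity peak table, its
#' annotation against an ion library, and the lipid-class summary over the
#' combined 90 entries.
#'
#' @param pos_spectra,neg_spectra Lists of normalized `roi_spectrum`
#'   objects (either may be empty).
#' @param library An `ion_library` for annotation.
#' @param n_top Peaks kept per polarity (default 45).
#' @param tol_ppm Annotation tolerance (default 100 ppm).
#' @param unique_species Collapse ionization forms in the class summary.
#' @param ... Passed to [pick_peaks()].
#' @return List with `peak_table` (combined, annotated: extra columns
#'   `best_name`, `ion_form`, `ppm`), `assignments`, `summary`
#'   (a `class_summary`), and `peaks_detected` (count per polarity).
#' @export
run_profile <- function(pos_spectra, neg_spectra, library,
                        n_top = 45L, tol_ppm = 100,
                        unique_species = FALSE, ...) {
  tabs <- list(); anns <- list(); detected <- c()
  for (spectra in list(pos_spectra, neg_spectra)) {
    if (!length(spectra)) next
    ms <- mean_spectrum(spectra)
    pk <- pick_peaks(ms, ...)
    detected[if (ms$polarity > 0) "positive" else "negative"] <- nrow(pk)
    tab <- top_n_peaks(pk, ms, n = n_top)
    ann <- annotate(tab$mz, library, tol_ppm = tol_ppm,
                    polarity = ms$polarity)
    tabs[[length(tabs) + 1L]] <- tab
    anns <- c(anns, ann)
  }
  if (!length(tabs)) stop("no ROI spectra supplied")
  combined <- do.call(rbind, tabs)
  rep <- annotation_report(anns)
  combined$best_name <- rep$best_name
  combined$ion_form <- rep$ion_form
  combined$ppm <- rep$ppm
  list(peak_table = combined, assignments = anns,
       summary = class_summary(combined, anns,
                               unique_species = unique_species),
       peaks_detected = detected)
}

#' Turnover pipeline for one treated-vs-control comparison
#'
#' The second deliverable: peak picking on the pooled mean spectrum,
#' mean-centered PCA over the peak features, selection of the discriminant
#' peaks from the loadings of the best group-separating component, then
#' per-peak two-sided Mann-Whitney tests with direction calls, annotation
#' and isotope-shift flags.
#'
#' @param treated,control Lists of normalized `roi_spectrum` objects
#'   sharing one axis and polarity.
#' @param library Optional `ion_library` for annotation/isotope flags.
#' @param top_fraction Fraction of peak features selected by |loading|
#'   (default 0.15: a selection budget of roughly twice the number of
#'   label-affected peaks expected under the default ten-species
#'   incorporation map, so both the labeled peaks and their depleted
#'   unlabeled counterparts survive selection).
#' @param alpha Significance level on (raw) p-values.
#' @param adjust `"none"` or `"BH"`.
#' @param scale PCA scaling (`"none"`, `"uv"`, `"pareto"`).
#' @param test_all Skip the PCA filter and test every picked peak.
#' @param tol_ppm Annotation tolerance.
#' @param ... Passed to [pick_peaks()].
#' @return A `turnover_table`; attributes `feature_bins`, `selected_bins`,
#'   `component`, `t_stat`.
#' @export
run_turnover <- function(treated, control, library = NULL,
                         top_fraction = 0.15, alpha = 0.05,
                         adjust = c("none", "BH"),
                         scale = "none", test_all = FALSE,
                         tol_ppm = 100, ...) {
  adjust <- match.arg(adjust)
  stopifnot(length(treated) >= 2, length(control) >= 2)
  all_spec <- c(treated, control)
  pol <- unique(vapply(all_spec, `[[`, integer(1), "polarity"))
  if (length(pol) != 1) stop("treated and control must share one polarity")
  ax <- all_spec[[1]]$axis
  ms <- mean_spectrum(all_spec)
  pk <- pick_peaks(ms, ...)
  if (!nrow(pk)) stop("no peaks detected in the pooled mean spectrum")
  bins <- pk$bin
  mat <- do.call(rbind, lapply(all_spec, function(s) s$normalized[bins]))
  groups <- rep(c("treated", "control"), c(length(treated), length(control)))

  if (test_all) {
    sel <- seq_along(bins)
    comp <- NA_integer_; tstat <- NA_real_
  } else {
    dec <- pca_spectra(mat, center = TRUE, scale = scale)
    sel <- select_discriminant_peaks(dec, groups,
                                     top_fraction = top_fraction)
    comp <- attr(sel, "component"); tstat <- attr(sel, "t_stat")
    if (!length(sel)) {
      sel <- integer(0)
    }
  }
  if (!length(sel)) {
    out <- turnover_table(mat[groups == "treated", , drop = FALSE],
                          mat[groups == "control", , drop = FALSE],
                          bins, ax, library, selected = integer(0),
                          alpha = alpha, adjust = adjust,
                          tol_ppm = tol_ppm, test_all = TRUE)
    out$significant <- FALSE & out$significant
    attr(out, "note") <- "no discriminant component; nothing selected"
  } else {
    out <- turnover_table(mat[groups == "treated", , drop = FALSE],
                          mat[groups == "control", , drop = FALSE],
                          bins, ax, library, selected = sel,
                          alpha = alpha, adjust = adjust,
                          tol_ppm = tol_ppm, test_all = test_all)
  }
  attr(out, "feature_bins") <- bins
  attr(out, "selected_bins") <- bins[sel]
  attr(out, "component") <- comp
  attr(out, "t_stat") <- tstat
  out
}

#' Write a result table as TSV with a provenance header
#'
#' Output files carry comment lines recording the package version and a
#' digest of the parameters that produced them, so a run can be matched to
#' its configuration.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param params Named list of parameters recorded in the header.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, params = list()) {
  digest <- fnv_hex(fnv_hash(paste(deparse(params), collapse = "")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# simslipid %s", as.character(utils::packageVersion("simslipid"))),
    sprintf("# params %s", digest)
  ), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
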