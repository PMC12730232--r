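#' PCA of ROI spectra
#'
#' Singular value decomposition of the (optionally scaled) mean-centered
#' spectra-by-bins matrix. Components with zero singular value are dropped,
#' so identical spectra yield zero components; at most `min(n - 1, p)`
#' components are returned.
#'
#' @param mat Numeric matrix, rows = ROI spectra, columns = features
#'   (retained bins, or picked peaks).
#' @param center Mean-center columns (default TRUE).
#' @param scale `"none"` (default), `"uv"` (unit variance) or `"pareto"`
#'   (1/sqrt(sd)).
#' @return List with `scores` (n x k), `loadings` (p x k, orthonormal),
#'   `sdev`, `explained` (fraction of variance per component), `center`,
#'   `scale_values`.
#' @export
pca_spectra <- function(mat, center = TRUE, scale = c("none", "uv", "pareto")) {
  scale <- match.arg(scale)
  stopifnot(nrow(mat) >= 3)
  ctr <- if (center) colMeans(mat) else rep(0, ncol(mat))
  x <- sweep(mat, 2, ctr)
  sv <- rep(1, ncol(mat))
  if (scale != "none") {
    s <- apply(x, 2, stats::sd)
    sv <- if (scale == "uv") s else sqrt(s)
    sv[sv == 0] <- 1
    x <- sweep(x, 2, sv, "/")
  }
  k_max <- min(nrow(x) - 1L, ncol(x))
  dec <- svd(x, nu = k_max, nv = k_max)
  d <- dec$d[seq_len(k_max)]
  keep <- d > max(d[1], 0) * 1e-10 & d > 0
  if (!any(keep)) {
    return(list(scores = matrix(0, nrow(x), 0), loadings = matrix(0, ncol(x), 0),
                sdev = numeric(0), explained = numeric(0),
                center = ctr, scale_values = sv))
  }
  d <- d[keep]
  u <- dec$u[, keep, drop = FALSE]
  v <- dec$v[, keep, drop = FALSE]
  scores <- u %*% diag(d, length(d))
  list(scores = scores, loadings = v,
       sdev = d / sqrt(max(1, nrow(x) - 1)),
       explained = d^2 / sum(dec$d^2),
       center = ctr, scale_values = sv)
}

#' Select discriminant peaks from PCA loadings
#'
#' Chooses the component whose scores best separate the two groups (largest
#' absolute two-sample t statistic) and returns the features in the top
#' `top_fraction` of absolute loading on that component. If no component
#' separates the groups (max |t| < `min_t`), an empty selection is returned
#' with a warning.
#'
#' @param pca Result of [pca_spectra()].
#' @param groups Factor/vector with two levels, one per spectrum (row).
#' @param top_fraction Fraction of features to keep, by |loading|.
#' @param min_t Minimum |t| for a component to count as separating.
#' @return Integer vector of selected feature (column) indices, ascending;
#'   attributes `component` and `t_stat`.
#' @export
select_discriminant_peaks <- function(pca, groups, top_fraction = 0.05,
                                      min_t = 1) {
  g <- as.factor(groups)
  stopifnot(nlevels(g) == 2, nrow(pca$scores) == length(g))
  if (ncol(pca$scores) == 0) {
    warning("no variance: empty selection")
    return(structure(integer(0), component = NA_integer_, t_stat = NA_real_))
  }
  tstat <- apply(pca$scores, 2, function(s) {
    a <- s[g == levels(g)[1]]; b <- s[g == levels(g)[2]]
    se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    if (se == 0) return(if (mean(a) == mean(b)) 0 else Inf)
    (mean(a) - mean(b)) / se
  })
  comp <- which.max(abs(tstat))
  if (abs(tstat[comp]) < min_t) {
    warning("no component separates the groups (max |t| = ",
            signif(abs(tstat[comp]), 3), "); empty selection")
    return(structure(integer(0), component = comp, t_stat = tstat[comp]))
  }
  load <- abs(pca$loadings[, comp])
  k <- max(1L, ceiling(top_fraction * length(load)))
  sel <- sort(order(-load, method = "radix")[seq_len(k)])
  structure(sel, component = comp, t_stat = tstat[comp])
}

#' Mann-Whitney U test (two-sided)
#'
#' U computed from rank sums with midranks for ties. The p-value comes from
#' exact enumeration of all group assignments of the observed values when
#' `n1 + n2 <= exact_limit` (ties handled exactly), otherwise from the
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction. Identical samples give p = 1.
#'
#' @param x,y Numeric samples (treated, control), each of length >= 2.
#' @param exact_limit Largest `n1 + n2` for which the exact permutation
#'   distribution is enumerated (default 20).
#' @return List with `U` (for `x`), `p` (two-sided), `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney_u <- function(x, y, exact_limit = 20L) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  r <- rank(c(x, y))  # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_limit) {
    U_all <- enumerate_u(c(x, y), n1)
    p <- mean(abs(U_all - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    N <- n1 + n2
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  list(U = U, p = p, method = method)
}

# U statistics of every assignment of n1 of the pooled values to group 1.
enumerate_u <- function(pooled, n1) {
  r <- rank(pooled)
  combos <- utils::combn(length(pooled), n1)
  colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
}

#' Per-peak turnover table for a treated-vs-control comparison
#'
#' For each selected feature bin: a two-sided Mann-Whitney test on the
#' TIC-normalized intensities, a direction call from the group means, the
#' best library annotation, and an isotope-shift flag marking bins that sit
#' one label shift above an unlabeled library ion (the signature of
#' precursor incorporation). Significance is `p <= alpha` on raw p-values
#' by default; Benjamini-Hochberg adjusted p-values are reported alongside
#' and used instead when `adjust = "BH"`.
#'
#' @param treated,control Matrices (spectra x bins) of normalized
#'   intensities over the same feature bins.
#' @param bins Feature bin indices (columns), on `axis`.
#' @param axis The shared [mass_axis()].
#' @param library Optional `ion_library` for annotation.
#' @param selected Optional integer indices (into `bins`) flagged as
#'   PCA-selected; rows outside it are still tested when
#'   `test_all = TRUE`, otherwise only selected bins are tested.
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param tol_ppm Annotation and isotope-flag tolerance.
#' @param label_deltas Named vector of label mass shifts to flag (defaults:
#'   one 13C, two 13C, one 15N).
#' @param test_all Test all bins, ignoring the selection filter.
#' @return A `turnover_table` data frame.
#' @export
turnover_table <- function(treated, control, bins, axis, library = NULL,
                           selected = seq_along(bins), alpha = 0.05,
                           adjust = c("none", "BH"), tol_ppm = 100,
                           label_deltas = c(c13_1 = SHIFT_13C,
                                            c13_2 = 2 * SHIFT_13C,
                                            n15_1 = SHIFT_15N),
                           test_all = FALSE) {
  adjust <- match.arg(adjust)
  stopifnot(ncol(treated) == length(bins), ncol(control) == length(bins))
  idx <- if (test_all) seq_along(bins) else sort(unique(selected))
  if (!length(idx)) stop("no peaks selected for testing")
  mz <- bin_centers(axis, bins[idx])

  tests <- lapply(idx, function(j)
    mann_whitney_u(treated[, j], control[, j]))
  p <- vapply(tests, `[[`, numeric(1), "p")
  U <- vapply(tests, `[[`, numeric(1), "U")
  m_t <- colMeans(treated[, idx, drop = FALSE])
  m_c <- colMeans(control[, idx, drop = FALSE])
  p_adj <- stats::p.adjust(p, method = "BH")

  ann <- if (!is.null(library)) {
    rep <- annotation_report(annotate(mz, library, tol_ppm = tol_ppm))
    rep[, c("best_name", "ion_form", "theoretical_mz", "ppm")]
  } else {
    data.frame(best_name = NA_character_, ion_form = NA_character_,
               theoretical_mz = NA_real_, ppm = NA_real_)[rep(1, length(idx)), ]
  }

  iso <- rep(FALSE, length(idx))
  if (!is.null(library)) {
    unlab <- library$mz[vapply(library$ion, function(ti)
      is.null(ti$species$label), logical(1))]
    for (i in seq_along(idx)) {
      for (d in label_deltas) {
        if (any(abs(ppm_error(mz[i], unlab + d)) <= tol_ppm)) {
          iso[i] <- TRUE; break
        }
      }
    }
  }

  out <- data.frame(
    bin = bins[idx], mz = mz,
    mean_treated = m_t, mean_control = m_c,
    direction = ifelse(m_t > m_c, "increase",
                       ifelse(m_t < m_c, "decrease", "none")),
    U = U, p = p, p_adj = p_adj,
    significant = (if (adjust == "BH") p_adj else p) <= alpha,
    selected = idx %in% selected,
    isotope_shift = iso,
    row.names = NULL
  )
  out <- cbind(out, ann, row.names = NULL)
  class(out) <- c("turnover_table", class(out))
  out
}

#' Side-by-side comparison of two precursor arms against a shared control
#'
#' Joins two turnover tables on the feature bin, keeping each arm's
#' direction, p-value and significance call (the layout of two-precursor
#' comparison figures).
#'
#' @param a,b `turnover_table` results computed on the same mass axis.
#' @param suffixes Column suffixes for the two arms.
#' @return Merged data frame, one row per bin present in either arm.
#' @export
compare_conditions <- function(a, b, suffixes = c("_a", "_b")) {
  if (!isTRUE(all.equal(attr(a, "axis_id", exact = TRUE),
                        attr(b, "axis_id", exact = TRUE))) &&
      length(intersect(a$bin, b$bin)) > 0) {
    mza <- a$mz[match(intersect(a$bin, b$bin), a$bin)]
    mzb <- b$mz[match(intersect(a$bin, b$bin), b$bin)]
    if (any(abs(mza - mzb) > 1e-9))
      stop("turnover tables do not share a mass axis")
  }
  cols <- c("mz", "direction", "U", "p", "p_adj", "significant",
            "isotope_shift", "best_name", "ion_form")
  merge(a[, c("bin", cols)], b[, c("bin", cols)],
        by = "bin", all = TRUE, suffixes = suffixes)
}
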