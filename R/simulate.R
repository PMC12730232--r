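#' Ground-truth lipidome of the synthetic datacube generator
#'
#' A curated table of membrane lipid ions emulating the composition of
#' cultured midbrain neurons: 65 ions per polarity, of which the 45 most
#' intense per polarity follow the class mix observed in such cells
#' (over the 90 top entries: ~33% PC, ~11% PS, ~11% Cer, ~9% SHexCer,
#' ~9% PE, remainder spread over FA/PI/LPI/DG/MG/HexCer/LPA/LPE/PG),
#' plus 20 lower-intensity entries per polarity. Includes the
#' phosphocholine-headgroup fragment at m/z 184.07 (the positive-mode cell
#' marker) and the fatty-acid markers at 255.23/283.26 (negative mode).
#' All m/z values are computed by the package's ion calculus.
#'
#' @return An `ion_library` data frame with an extra `rel_intensity`
#'   column (arbitrary units) and `tier` (`"major"`/`"minor"`).
#' @export
default_lipidome <- function() {
  e <- function(name, ions, ef = NA_character_) data.frame(
    name = name, ions = ions, explicit_formula = ef, stringsAsFactors = FALSE)

  # -- positive mode: 45 majors -------------------------------------------
  pos_major <- rbind(
    # 30 PC entries (molecular ions, salt adducts, headgroup fragment)
    e("C5H15PNO4", "+"),              # PC headgroup marker, class set below
    e("PC 38:2", "+H"),  e("PC 36:2", "+Na"), e("PC 38:4", "+Na"),
    e("PC 34:1", "+H"),  e("PC 34:1", "+Na"), e("PC 34:1", "+K"),
    e("PC 32:0", "+H"),  e("PC 32:0", "+K"),  e("PC 32:1", "+H"),
    e("PC 32:1", "+K"),  e("PC 36:1", "+H"),  e("PC 36:1", "+K"),
    e("PC 34:0", "+H"),  e("PC 34:0", "+Na"), e("PC 36:2", "+H"),
    e("PC 38:4", "+H"),  e("PC 36:4", "+K"),  e("PC 36:4", "+Na"),
    e("PC 38:6", "+H"),  e("PC 40:6", "+H"),  e("PC 30:0", "+H"),
    e("PC 30:1", "+K"),  e("PC 32:2", "+H"),  e("PC 34:2", "+H"),
    e("PC 34:2", "+Na"), e("PC 36:0", "+H"),  e("PC 38:5", "+K"),
    e("PC 40:4", "+H"),  e("PC 34:1", "-TMA+K"),
    # 10 Cer entries
    e("Cer 34:1;O2", "+H"), e("Cer 34:1;O2", "+K"), e("Cer 36:1;O2", "+H"),
    e("Cer 38:1;O", "+Na"), e("Cer 38:2;O2", "+H"), e("Cer 40:1;O2", "+H"),
    e("Cer 42:1;O2", "+H"), e("Cer 42:2;O2", "+H"), e("Cer 34:1;O4", "+H"),
    e("Cer 40:2;O2", "+Na"),
    # 5 others
    e("DG 34:3", "+H-H2O"), e("DG 36:2", "+H-H2O"), e("MG 20:5", "+K"),
    e("HexCer 32:2;O3", "+Na"), e("HexCer 30:2;O2", "+K")
  )
  # -- positive mode: 20 minors -------------------------------------------
  pos_minor <- rbind(
    e("PC 16:4", "+H"),   e("PC 28:0", "+H"),   e("PC 40:2", "+H"),
    e("PC 42:6", "+H"),   e("PE 34:3", "+H"),   e("PG 22:4", "+H"),
    e("PG 34:0", "+H"),  e("SM 34:1;O2", "+H"), e("SM 36:1;O2", "+H"),
    e("TG 48:2", "+Na"),  e("TG 52:3", "+Na"),  e("DG 36:4", "+H-H2O"),
    e("MG 18:1", "+H"),   e("Cer 38:1;O2", "+Na"), e("Cer 36:2;O2", "+K"),
    e("HexCer 34:1;O2", "+H"), e("CerPE 32:2;O2", "+Na"),
    e("CerPE 40:4;O2", "+H"), e("LPC 16:0", "+K"), e("LPC 18:0", "+H")
  )
  # -- negative mode: 45 majors -------------------------------------------
  neg_major <- rbind(
    # 10 PS
    e("PS 36:1", "-87-H"), e("PS 36:1", "-H"), e("PS 40:6", "-H"),
    e("PS 44:8", "-H"),   e("PS 38:4", "-H"),  e("PS 36:0", "-H"),
    e("PS 42:7", "-H"),   e("PS 44:12", "-H"), e("PS 40:0", "-H"),
    e("PS 34:1", "-H"),
    # 8 SHexCer
    e("SHexCer 42:2;O2", "-H"), e("SHexCer 36:1;O2", "-H"),
    e("SHexCer 44:2;O2", "-H"), e("SHexCer 40:1;O2", "-H"),
    e("SHexCer 42:1;O2", "-H"), e("SHexCer 34:1;O2", "-H"),
    e("SHexCer 36:0;O2", "-H"), e("SHexCer 36:2;O2", "-H"),
    # 8 PE
    e("PE 34:1", "-H"), e("PE 36:1", "-H"), e("PE 36:2", "-H"),
    e("PE 38:4", "-H"), e("PE 38:5", "-H"), e("PE 36:4", "-H"),
    e("PE O-38:5", "-H"), e("PE 34:2", "-H"),
    # 5 FA (incl. both negative-mode markers)
    e("FA 16:0", "-H"), e("FA 18:0", "-H"), e("FA 18:1", "-H"),
    e("FA 16:1", "-H"), e("FA 20:4", "-H"),
    # 6 PI
    e("PI 38:4", "-H"), e("PI 38:3", "-H"), e("PI 38:5", "-H"),
    e("PI 36:2", "-H"), e("PI 34:1", "-H"), e("PI 40:6", "-H"),
    # 3 LPI, 2 LPA, 2 LPE, 1 PG
    e("LPI 18:0", "-H"), e("LPI O-18:2", "-H"), e("LPI 20:4", "-H"),
    e("LPA 20:4", "-H"), e("LPA 16:1", "-H"),
    e("LPE 18:3", "-H"), e("LPE 22:6", "-H"),
    e("PG 36:2", "-H")
  )
  # -- negative mode: 20 minors -------------------------------------------
  neg_minor <- rbind(
    e("ST 28:4;O6", "-H", "C28H42O6"),
    e("FA 12:0", "-H"),  e("FA 14:0", "-H"),  e("FA 20:0", "-H"),
    e("FA 22:6", "-H"),  e("FA 18:3;O", "-H"),
    e("PA 24:2;O3", "-H"), e("PA 36:2", "-H"),
    e("PS 20:0;O", "-H"), e("PS 44:0", "-H"), e("PS 44:13", "-H"),
    e("PI 40:5", "-H"),  e("PI 40:4", "-H"),  e("PI 38:2", "-H"),
    e("LPS 18:1", "-H"), e("LPG 18:1", "-H"),
    e("LPE 26:6", "-H"), e("Cer 38:0;O", "-H"),
    e("HexCer 40:1;O2", "-H"), e("SHexCer 38:2;O2", "-H")
  )

  blocks <- list(pos_major = pos_major, pos_minor = pos_minor,
                 neg_major = neg_major, neg_minor = neg_minor)
  libs <- lapply(names(blocks), function(b) {
    tab <- blocks[[b]]
    tab$explicit_formula[is.na(tab$explicit_formula)] <- ""
    lib <- build_ion_library(tab)
    major <- grepl("major", b)
    nr <- nrow(lib)
    # geometric intensity ladder within each tier, distinct ranks
    lib$rel_intensity <- if (major) 1000 * 0.95^(seq_len(nr) - 1)
                         else 8 * 0.97^(seq_len(nr) - 1)
    lib$tier <- if (major) "major" else "minor"
    lib
  })
  out <- do.call(rbind, libs)
  # the headgroup fragment belongs to the PC class for summaries
  out$class[out$class == "formula" & grepl("^C5H15", out$name)] <- "PC"
  out$name[grepl("^C5H15", out$name)] <- "PC headgroup"
  class(out) <- c("ion_library", class(out))
  out
}

#' Default precursor incorporation maps
#'
#' One entry per labeled-precursor arm: the label type carried by the
#' precursor and the species whose ions receive the label. Incorporation
#' moves a fraction `f` of each targeted ion's expected intensity from its
#' bin to the bin one label shift higher (a pseudo-steady state after a
#' multi-day incubation, not a kinetic model).
#'
#' @param f Incorporation fraction applied to every target (default 0.3).
#' @return Named list of arms, each `list(label =, targets = data.frame)`.
#' @export
default_incorporation <- function(f = 0.3) {
  tg <- function(names) data.frame(name = names, f = f,
                                   stringsAsFactors = FALSE)
  list(
    "13C-stearic" = list(
      label = "c13:1",
      targets = tg(c("PC 34:1", "PC 32:0", "PC 36:1", "PC 30:1",
                     "Cer 34:1;O2",
                     "FA 18:0", "PI 34:1", "PS 36:1", "LPI 18:0",
                     "FA 18:1"))),
    "13C-lauric" = list(
      label = "c13:1",
      targets = tg(c("PC 30:0", "PC 32:1", "PC 28:0", "PG 36:2",
                     "Cer 34:1;O2", "FA 16:0", "PS 34:1", "PI 34:1",
                     "LPA 16:1", "FA 12:0"))),
    "13C-linoleic" = list(
      label = "c13:1",
      targets = tg(c("PI 38:5", "PI 34:1", "LPI 20:4", "PS 44:12",
                     "PS 36:1", "DG 34:3", "PC 36:2", "FA 16:1",
                     "LPA 16:1", "FA 16:0"))),
    "13C-linolenic" = list(
      label = "c13:1",
      targets = tg(c("Cer 34:1;O2", "Cer 38:2;O2", "PS 38:4", "PS 36:0",
                     "PE 34:3", "PG 34:0", "FA 18:3;O", "SM 34:1;O2",
                     "LPA 16:1", "FA 20:4"))),
    "13C2-ethanolamine" = list(
      label = "c13:2",
      targets = tg(c("CerPE 32:2;O2", "CerPE 40:4;O2", "PE 34:1",
                     "PE 36:1", "PE 38:4", "PE O-38:5", "LPE 18:3",
                     "LPE 22:6", "PS 34:1", "PS 40:6"))),
    "15N-choline" = list(
      label = "n15:1",
      targets = tg(c("PC headgroup", "PC 34:1", "PC 32:0", "PC 32:1",
                     "PC 36:1", "PC 34:0", "PC 38:2", "LPC 16:0",
                     "LPC 18:0", "SM 34:1;O2")))
  )
}

#' Configuration of a synthetic ToF-SIMS experiment
#'
#' Bundles the generative model parameters: image geometry, cell geometry,
#' the ground-truth lipidome, precursor incorporation maps, substrate and
#' chemical background, count statistics and the seed.
#'
#' @param nx,ny Image size in pixels (default 128 x 128).
#' @param n_cells Cells per field of view.
#' @param cell_axes Ellipse semi-axes in pixels (mean values; jittered).
#' @param lipidome An `ion_library` with `rel_intensity` (default
#'   [default_lipidome()]).
#' @param incorporation Arm map (default [default_incorporation()]).
#' @param counts_per_pixel Mean total lipid counts per cell pixel.
#' @param bg_total Mean chemical-background counts per pixel (spread over
#'   `n_bg_bins` fixed pseudo-random bins, emulating the quasi-discrete
#'   hydrocarbon background of SIMS spectra).
#' @param n_bg_bins Number of background bins.
#' @param substrate_total Mean substrate-ion counts per background pixel,
#'   split over the interference peaks of [default_interference_mzs()].
#' @param bio_cv Lognormal coefficient of variation of per-ROI,
#'   per-species biological intensity factors.
#' @param roi_pixels Mean cell area (pixels) used by
#'   [simulate_roi_spectra()].
#' @param axis Mass axis (default 100-1000 Da, 0.05-Da bins).
#' @param seed Mandatory integer seed; every generator call derives its
#'   RNG stream from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(nx = 128L, ny = 128L, n_cells = 5L,
                       cell_axes = c(8, 6),
                       lipidome = default_lipidome(),
                       incorporation = default_incorporation(),
                       counts_per_pixel = 600,
                       bg_total = 30, n_bg_bins = 400L,
                       substrate_total = 150,
                       bio_cv = 0.2,
                       roi_pixels = 130,
                       axis = mass_axis(), seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(all(vapply(incorporation, function(a)
    all(a$targets$f >= 0 & a$targets$f <= 1), logical(1))))
  bins <- bin_of(axis, lipidome$mz)
  if (any(is.na(bins)))
    stop("lipidome ion m/z outside the mass axis: ",
         paste(lipidome$name[is.na(bins)], collapse = ", "))
  cfg <- list(nx = as.integer(nx), ny = as.integer(ny),
              n_cells = as.integer(n_cells), cell_axes = cell_axes,
              lipidome = lipidome, incorporation = incorporation,
              counts_per_pixel = counts_per_pixel, bg_total = bg_total,
              n_bg_bins = as.integer(n_bg_bins),
              substrate_total = substrate_total,
              bio_cv = bio_cv, roi_pixels = roi_pixels,
              axis = axis, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic sub-seed for a named generator call (stays < 2^31).
sub_seed <- function(config, ...) {
  key <- paste(c(config$seed, ...), collapse = "/")
  as.integer(fnv_hash(key) %% 2147483647)
}

# Expected per-pixel intensity table for one arm and polarity:
# data frame (bin, intensity) incl. label transfer, plus the truth bins.
arm_expectation <- function(config, arm, polarity) {
  lib <- config$lipidome[config$lipidome$polarity == polarity, , drop = FALSE]
  scale <- config$counts_per_pixel / sum(config$lipidome$rel_intensity)
  base <- lib$rel_intensity * scale
  bins <- bin_of(config$axis, lib$mz)

  shifted_bins <- integer(0)
  source_bins <- integer(0)
  extra <- data.frame(bin = integer(0), intensity = numeric(0))
  if (arm != "control") {
    if (!arm %in% names(config$incorporation))
      stop("unknown arm: '", arm, "'")
    spec <- config$incorporation[[arm]]
    delta <- label_shift(spec$label)
    hit <- match(lib$name, spec$targets$name)
    f <- ifelse(is.na(hit), 0, spec$targets$f[hit])
    lab_mz <- lib$mz + delta
    lab_bin <- bin_of(config$axis, lab_mz)
    moved <- f * base
    take <- moved > 0
    if (any(is.na(lab_bin[take])))
      stop("labeled ion m/z outside the mass axis for arm ", arm)
    base <- base * (1 - f)
    extra <- data.frame(bin = lab_bin[take], intensity = moved[take])
    shifted_bins <- sort(unique(lab_bin[take]))
    source_bins <- sort(unique(bins[take]))
  }
  tab <- rbind(data.frame(bin = bins, intensity = base), extra)
  tab <- stats::aggregate(intensity ~ bin, tab, sum)
  list(cell = tab, lib = lib, lib_bins = bins,
       shifted_bins = shifted_bins, source_bins = source_bins)
}

# Fixed pseudo-random background bins (identical across arms/replicates so
# control and treated share the same expected background structure).
background_bins <- function(config, polarity, exclude) {
  set.seed(sub_seed(config, "bg-bins", polarity))
  pool <- setdiff(seq_len(config$axis$n_bins), exclude)
  sort(sample(pool, min(config$n_bg_bins, length(pool))))
}

# Ellipse cell masks placed without overlap; deterministic given the seed.
place_cells <- function(config, arm, polarity, image_index) {
  set.seed(sub_seed(config, "cells", arm, polarity, image_index))
  nx <- config$nx; ny <- config$ny
  a0 <- config$cell_axes[1]; b0 <- config$cell_axes[2]
  masks <- list(); centers <- NULL
  tries <- 0
  while (length(masks) < config$n_cells && tries < 2000) {
    tries <- tries + 1
    a <- a0 * stats::runif(1, 0.8, 1.2)
    b <- b0 * stats::runif(1, 0.8, 1.2)
    cx <- stats::runif(1, a + 2, nx - a - 1)
    cy <- stats::runif(1, b + 2, ny - b - 1)
    sep <- min(2.4 * max(a0, b0),
               (min(nx, ny) - 2 * max(a0, b0) - 4) / 2)
    if (!is.null(centers) &&
        any(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) < sep)) next
    col <- matrix(rep(seq_len(nx), each = ny), ny, nx)
    row <- matrix(rep(seq_len(ny), nx), ny, nx)
    mask <- ((col - cx) / a)^2 + ((row - cy) / b)^2 <= 1
    if (sum(mask) < 10) next
    masks[[length(masks) + 1L]] <- mask
    centers <- rbind(centers, c(cx, cy))
  }
  if (length(masks) < config$n_cells)
    warning("placed only ", length(masks), " of ", config$n_cells, " cells")
  masks
}

#' Render one synthetic datacube (one arm, one polarity)
#'
#' Expected per-pixel spectrum: inside cells, the arm's lipidome
#' expectation (with the incorporation fraction moved to the label-shifted
#' bin) scaled by a per-cell, per-ion lognormal biological factor; on
#' substrate pixels, the interference peaks; everywhere, the chemical
#' background. Counts are Poisson draws unless `noiseless = TRUE`, which
#' returns the expectations themselves.
#'
#' @param config A [sim_config()].
#' @param arm `"control"` or a name of `config$incorporation`.
#' @param polarity `+1` or `-1`.
#' @param image_index Replicate/field index (varies the RNG stream).
#' @param noiseless Return expected intensities instead of Poisson counts.
#' @return A `spectral_image`; attribute `"ground_truth"` holds cell masks,
#'   the per-ion bins, and the arm's shifted/source bins.
#' @export
render_arm <- function(config, arm = "control", polarity = 1L,
                       image_index = 1L, noiseless = FALSE) {
  ex <- arm_expectation(config, arm, polarity)
  masks <- place_cells(config, arm, polarity, image_index)
  nx <- config$nx; ny <- config$ny
  npx <- nx * ny

  cell_px <- lapply(masks, function(m) which(t(m)))
  all_cell <- unlist(cell_px)
  bg_px <- setdiff(seq_len(npx), all_cell)

  sub_mzs <- default_interference_mzs(polarity)
  sub_bins <- bin_of(config$axis, sub_mzs)
  bgb <- background_bins(config, polarity,
                         exclude = c(ex$cell$bin, sub_bins))
  bg_rate <- config$bg_total / length(bgb)
  sub_rate <- config$substrate_total / length(sub_bins)

  set.seed(sub_seed(config, "counts", arm, polarity, image_index))
  ii <- list(); jj <- list(); xx <- list()
  push <- function(i, j, x) {
    keep <- x > 0
    if (!any(keep)) return(invisible(NULL))
    ii[[length(ii) + 1L]] <<- i[keep]
    jj[[length(jj) + 1L]] <<- j[keep]
    xx[[length(xx) + 1L]] <<- x[keep]
    invisible(NULL)
  }

  # cells: per-cell lognormal biological factor per ion bin
  sdlog <- sqrt(log(1 + config$bio_cv^2))
  for (ci in seq_along(masks)) {
    factors <- stats::rlnorm(nrow(ex$cell), meanlog = -sdlog^2 / 2,
                             sdlog = sdlog)
    lam <- ex$cell$intensity * factors
    px <- cell_px[[ci]]
    lam_mat <- outer(lam, rep(1, length(px)))  # bins x pixels
    vals <- if (noiseless) lam_mat else
      matrix(stats::rpois(length(lam_mat), lam_mat), nrow(lam_mat))
    nzk <- which(vals != 0, arr.ind = TRUE)
    push(px[nzk[, 2]], ex$cell$bin[nzk[, 1]], vals[nzk])
  }
  # substrate peaks on background pixels
  if (length(bg_px)) {
    for (b in sub_bins) {
      lam <- rep(sub_rate, length(bg_px))
      v <- if (noiseless) lam else stats::rpois(length(lam), lam)
      push(bg_px, rep(b, length(bg_px)), v)
    }
    # chemical background: everywhere
  }
  lam_bg <- bg_rate
  if (noiseless) {
    for (b in bgb) push(seq_len(npx), rep(b, npx), rep(lam_bg, npx))
  } else {
    # sparse Poisson: expected nonzeros npx * n_bg_bins * lam_bg
    n_events <- stats::rpois(1, npx * length(bgb) * lam_bg)
    if (n_events > 0) {
      epx <- sample.int(npx, n_events, replace = TRUE)
      ebn <- sample(bgb, n_events, replace = TRUE)
      push(epx, ebn, rep(1, n_events))
    }
  }

  counts <- Matrix::sparseMatrix(i = as.integer(unlist(ii)),
                                 j = as.integer(unlist(jj)),
                                 x = as.numeric(unlist(xx)),
                                 dims = c(npx, config$axis$n_bins))
  img <- spectral_image(counts, nx, ny, config$axis, polarity,
                        metadata = list(arm = arm,
                                        image_index = image_index))
  attr(img, "ground_truth") <- list(
    masks = masks,
    lib = ex$lib, lib_bins = ex$lib_bins,
    cell_expectation = ex$cell,
    shifted_bins = ex$shifted_bins, source_bins = ex$source_bins,
    background_bins = bgb, substrate_bins = sub_bins
  )
  img
}

#' Simulate ROI spectra directly (no imaging step)
#'
#' Draws the summed spectrum of whole cell areas under the same generative
#' model as [render_arm()]: expected ROI spectrum = cell area (pixels,
#' jittered per ROI) times the per-pixel arm expectation times per-ROI,
#' per-ion biological factors, plus the area's share of chemical
#' background; counts are Poisson. This is the fast path for
#' replicate-heavy power and calibration studies, equivalent in
#' distribution to rendering, segmenting and summing.
#'
#' @param config A [sim_config()].
#' @param arm,polarity As in [render_arm()].
#' @param n_rois Number of cell areas to draw.
#' @param stream Extra RNG stream tag (vary across replicates).
#' @param noiseless Expected values instead of Poisson counts.
#' @return List of normalized `roi_spectrum` objects (interference removal
#'   is a no-op here since substrate ions sit outside cell areas; spectra
#'   are TIC-normalized); attribute `"ground_truth"` as in [render_arm()].
#' @export
simulate_roi_spectra <- function(config, arm = "control", polarity = 1L,
                                 n_rois = 8L, stream = 1L,
                                 noiseless = FALSE) {
  ex <- arm_expectation(config, arm, polarity)
  sub_bins <- bin_of(config$axis, default_interference_mzs(polarity))
  bgb <- background_bins(config, polarity,
                         exclude = c(ex$cell$bin, sub_bins))
  bg_rate <- config$bg_total / length(bgb)
  sdlog <- sqrt(log(1 + config$bio_cv^2))

  set.seed(sub_seed(config, "roi", arm, polarity, stream))
  out <- vector("list", n_rois)
  for (r in seq_len(n_rois)) {
    area <- max(20, round(stats::rnorm(1, config$roi_pixels,
                                       0.1 * config$roi_pixels)))
    factors <- stats::rlnorm(nrow(ex$cell), meanlog = -sdlog^2 / 2,
                             sdlog = sdlog)
    lam <- area * ex$cell$intensity * factors
    raw <- numeric(config$axis$n_bins)
    raw[ex$cell$bin] <- if (noiseless) lam else
      stats::rpois(length(lam), lam)
    lam_bg <- rep(area * bg_rate, length(bgb))
    raw[bgb] <- raw[bgb] + if (noiseless) lam_bg else
      stats::rpois(length(bgb), lam_bg)
    s <- structure(list(
      roi_id = r, condition = arm, replicate = stream,
      polarity = as.integer(polarity), axis = config$axis,
      raw = raw, normalized = NULL, removed_bins = integer(0)
    ), class = "roi_spectrum")
    s <- remove_interference(s, default_interference_mzs(polarity))
    out[[r]] <- tic_normalize(s)
  }
  attr(out, "ground_truth") <- list(
    lib = ex$lib, lib_bins = ex$lib_bins, cell_expectation = ex$cell,
    shifted_bins = ex$shifted_bins, source_bins = ex$source_bins,
    background_bins = bgb)
  out
}

#' Generate a full synthetic experiment on disk
#'
#' Writes imzML/ibd datacubes for the control and the requested precursor
#' arms (both polarities, several fields of view per arm) plus a
#' ground-truth manifest JSON recording the configuration digest, the
#' per-ion theoretical m/z, expected intensities and the truly shifted
#' bins per arm. Deterministic: two runs with the same config produce
#' byte-identical manifests.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param arms Arm names to render besides `"control"`.
#' @param n_control_images,n_treated_images Fields of view per arm.
#' @return Path to the manifest, invisibly.
#' @export
generate_experiment <- function(config, dir,
                                arms = names(config$incorporation),
                                n_control_images = 4L,
                                n_treated_images = 2L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config_digest = config_digest(config),
    seed = config$seed,
    axis = unclass(config$axis),
    geometry = c(nx = config$nx, ny = config$ny),
    n_species = nrow(config$lipidome),
    lipidome = data.frame(
      name = config$lipidome$name, ion_form = config$lipidome$ion_form,
      mz = round(config$lipidome$mz, 6),
      polarity = config$lipidome$polarity,
      class = config$lipidome$class,
      rel_intensity = config$lipidome$rel_intensity),
    files = list(), arms = list()
  )
  all_arms <- c("control", arms)
  for (arm in all_arms) {
    n_img <- if (arm == "control") n_control_images else n_treated_images
    for (polarity in c(1L, -1L)) {
      ex <- arm_expectation(config, arm, polarity)
      manifest$arms[[arm]][[if (polarity > 0) "positive" else "negative"]] <-
        list(shifted_bins = ex$shifted_bins, source_bins = ex$source_bins)
      for (k in seq_len(n_img)) {
        img <- render_arm(config, arm, polarity, image_index = k)
        fn <- sprintf("%s_%s_f%02d.imzML", gsub("[^0-9A-Za-z]+", "-", arm),
                      if (polarity > 0) "pos" else "neg", k)
        write_imzml(img, file.path(dir, fn))
        manifest$files[[length(manifest$files) + 1L]] <- list(
          file = fn, arm = arm, polarity = polarity, field = k,
          n_cells = length(attr(img, "ground_truth")$masks))
      }
    }
  }
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mf)
}

# Short stable digest of a config (FNV-1a over its deparsed form).
config_digest <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "lipidome")]),
               collapse = "")
  txt <- paste0(txt, paste(config$lipidome$name, collapse = ","),
                paste(round(config$lipidome$mz, 6), collapse = ","))
  fnv_hex(fnv_hash(txt))
}
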