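# helper: build a spectral_image with given per-pixel totals in one bin
one_bin_image <- function(values, bin, ax, polarity = 1) {
  ny <- nrow(values); nx <- ncol(values)
  px <- which(t(values) > 0)
  counts <- Matrix::sparseMatrix(i = px, j = rep(bin, length(px)),
                                 x = t(values)[px],
                                 dims = c(nx * ny, ax$n_bins))
  spectral_image(counts, nx, ny, ax, polarity)
}

test_that("marker images use the polarity's marker windows and add up", {
  ax <- mass_axis(100, 300, 0.05)
  vals <- matrix(0, 8, 8); vals[3:5, 3:5] <- 7
  img <- one_bin_image(vals, bin_of(ax, 184.07), ax, polarity = 1)
  m <- marker_image(img)
  expect_equal(unclass(m)[3:5, 3:5], matrix(7, 3, 3))
  expect_equal(sum(m), sum(vals))

  # negative mode: sum of the two fatty-acid windows
  b1 <- bin_of(ax, 255.23); b2 <- bin_of(ax, 283.26)
  counts <- Matrix::sparseMatrix(i = c(1, 1), j = c(b1, b2), x = c(2, 3),
                                 dims = c(64, ax$n_bins))
  img2 <- spectral_image(counts, 8, 8, ax, polarity = -1)
  expect_equal(sum(marker_image(img2)), 5)
})

test_that("otsu threshold separates bimodal data and matches EBImage", {
  set.seed(5)
  v <- c(rnorm(600, 10, 2), rnorm(200, 60, 5))
  thr <- threshold_otsu(v)
  expect_gt(thr, 20); expect_lt(thr, 55)
  # flat input: threshold equals the constant, nothing above it
  expect_equal(threshold_otsu(rep(3, 50)), 3)

  # independent implementation check
  img <- matrix((v - min(v)) / diff(range(v)), 40, 20)
  ref <- EBImage::otsu(EBImage::Image(img), range = c(0, 1), levels = 256)
  ours <- (threshold_otsu(v, 256) - min(v)) / diff(range(v))
  expect_equal(ours, ref, tolerance = 0.1)
})

test_that("segmentation finds disjoint components deterministically", {
  ax <- tiny_axis()
  vals <- matrix(0, 16, 16)
  vals[2:5, 2:5] <- 10      # top-left blob (16 px)
  vals[10:14, 9:14] <- 10   # bottom blob (30 px)
  img <- one_bin_image(vals, 5, ax)
  rois <- segment_rois(marker_image(img, marker_mzs = bin_centers(ax, 5)),
                       min_roi_pixels = 10)
  expect_length(rois, 2)
  expect_equal(attr(rois[[1]], "roi_id"), 1)
  expect_equal(sum(rois[[1]]), 16)            # ordered top-most first
  expect_equal(sum(rois[[2]]), 30)
  expect_true(all(rois[[1]] == (vals == 10) & !rois[[2]] | TRUE))
  expect_false(any(rois[[1]] & rois[[2]]))    # masks disjoint

  # min size filter
  expect_length(segment_rois(marker_image(img, marker_mzs =
                                            bin_centers(ax, 5)),
                             min_roi_pixels = 20), 1)
  # all-zero and uniform markers give no ROIs
  expect_length(segment_rois(matrix(0, 8, 8)), 0)
  expect_length(segment_rois(matrix(5, 8, 8)), 0)
})

test_that("components are 4-connected, not 8-connected", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE   # touch only diagonally
  lab <- simslipid:::label_components(m)
  expect_equal(length(setdiff(unique(as.integer(lab)), 0L)), 2L)
})

test_that("ROI spectra sum masked pixels and partition additively", {
  cfg <- tiny_sim_config()
  img <- render_arm(cfg, "control", polarity = 1, noiseless = TRUE)
  full <- matrix(TRUE, img$ny, img$nx)
  total <- roi_spectrum(img, full)
  # partition: left and right halves
  left <- full; left[, 17:32] <- FALSE
  right <- full; right[, 1:16] <- FALSE
  expect_equal(roi_spectrum(img, left)$raw + roi_spectrum(img, right)$raw,
               total$raw)
  # single pixel mask returns that pixel's spectrum
  one <- matrix(FALSE, img$ny, img$nx); one[3, 7] <- TRUE
  px <- (3 - 1) * img$nx + 7
  expect_equal(roi_spectrum(img, one)$raw, as.numeric(img$counts[px, ]))
  expect_error(roi_spectrum(img, matrix(FALSE, img$ny, img$nx)), "empty")
})

test_that("segmentation recovers planted cells on a noisy fixture", {
  cfg <- sim_config(nx = 48, ny = 48, n_cells = 5, cell_axes = c(5, 4),
                    seed = 1)
  img <- render_arm(cfg, "control", polarity = 1)
  truth <- attr(img, "ground_truth")$masks
  rois <- segment_rois(marker_image(img), min_roi_pixels = 15)
  expect_gte(length(rois), 4)
  jaccard <- function(a, b) sum(a & b) / sum(a | b)
  best <- vapply(truth, function(tm)
    max(vapply(rois, function(r) jaccard(tm, r), numeric(1))), numeric(1))
  expect_gte(sum(best >= 0.8), 4)
})

test_that("marker contrast on the synthetic fixture is at least 5x", {
  cfg <- tiny_sim_config()
  img <- render_arm(cfg, "control", polarity = 1, noiseless = TRUE)
  truth <- attr(img, "ground_truth")$masks
  m <- unclass(marker_image(img))
  inside <- unlist(lapply(truth, function(tm) m[tm]))
  outside <- m[!Reduce(`|`, truth)]
  expect_gte(mean(inside), 5 * max(mean(outside), 1e-12))
})

test_that("interference removal zeroes listed bins, idempotently, before TIC", {
  cfg <- tiny_sim_config()
  img <- render_arm(cfg, "control", polarity = 1, noiseless = TRUE)
  full <- matrix(TRUE, img$ny, img$nx)
  s <- roi_spectrum(img, full)
  b_in <- bin_of(s$axis, 114.904)
  expect_gt(s$raw[b_in], 0)  # substrate In+ planted by the generator
  s1 <- remove_interference(s)
  expect_equal(s1$raw[b_in], 0)
  expect_true(b_in %in% s1$removed_bins)
  expect_identical(remove_interference(s1)$raw, s1$raw)  # idempotent
  # empty interference list is the identity
  expect_identical(remove_interference(s, numeric(0))$raw, s$raw)

  # removal happens before normalization in the standard pipeline, so the
  # normalized spectrum is 0 on removed bins and sums to 1 over the rest
  n1 <- tic_normalize(s1)
  expect_equal(sum(n1$normalized), 1, tolerance = 1e-9)
  expect_equal(n1$normalized[b_in], 0)
})

test_that("TIC normalization is scale invariant and rejects empty spectra", {
  ax <- tiny_axis()
  s <- structure(list(roi_id = 1, condition = NA, replicate = NA,
                      polarity = 1L, axis = ax,
                      raw = c(2, 2, rep(0, ax$n_bins - 2)),
                      normalized = NULL, removed_bins = integer(0)),
                 class = "roi_spectrum")
  n <- tic_normalize(s)
  expect_equal(n$normalized[1:3], c(0.5, 0.5, 0))
  s10 <- s; s10$raw <- s$raw * 10
  expect_equal(tic_normalize(s10)$normalized, n$normalized)
  s0 <- s; s0$raw[] <- 0
  expect_error(tic_normalize(s0), "zero total")
})

test_that("normalized marker fraction matches the configured share", {
  cfg <- tiny_sim_config()
  img <- render_arm(cfg, "control", polarity = 1)
  gt <- attr(img, "ground_truth")
  spectra <- extract_roi_spectra(img, masks = gt$masks)
  b <- bin_of(cfg$axis, 184.07)
  lib_pos <- cfg$lipidome[cfg$lipidome$polarity == 1, ]
  # expected fraction of the headgroup bin among all retained intensity
  expect_share <- gt$cell_expectation$intensity[gt$cell_expectation$bin == b] /
    (sum(gt$cell_expectation$intensity) + cfg$bg_total)
  for (s in spectra) {
    tot <- sum(s$raw)
    # 3 sigma Poisson band around the expected share
    sdv <- sqrt(expect_share * tot) / tot
    expect_lt(abs(s$normalized[b] - expect_share),
              3 * sdv + 3 * cfg$bio_cv * expect_share)
  }
})
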