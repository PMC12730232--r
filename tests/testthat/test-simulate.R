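# compact experiment for file-tree tests: low-mass species, short axis
small_config <- function(seed = 1L) {
  species <- data.frame(
    name = c("C5H15PNO4", "MG 12:0", "FA 12:0", "FA 16:0", "FA 18:0"),
    ions = c("+", "+H", "-H", "-H", "-H"),
    explicit_formula = "",
    stringsAsFactors = FALSE)
  lib <- build_ion_library(species)
  lib$rel_intensity <- c(100, 40, 30, 80, 60)
  lib$tier <- "major"
  inc <- list("13C-palmitate" = list(
    label = "c13:1",
    targets = data.frame(name = "FA 16:0", f = 0.5)))
  sim_config(nx = 16L, ny = 16L, n_cells = 2L, cell_axes = c(3, 2),
             lipidome = lib, incorporation = inc,
             axis = mass_axis(100, 320, 0.05), n_bg_bins = 60L,
             seed = seed)
}

test_that("the default lipidome covers both polarities with exact class mix", {
  lib <- default_lipidome()
  expect_gte(sum(lib$polarity == 1), 60L)
  expect_gte(sum(lib$polarity == -1), 60L)
  # contains the flagship ions of each polarity
  expect_true(any(lib$polarity == 1 &
                    abs(ppm_error(814.63, lib$mz)) <= 100))
  expect_true(any(lib$polarity == -1 &
                    abs(ppm_error(885.55, lib$mz)) <= 100))
  # top-45 class mix per polarity is the configured one, exactly
  top90 <- do.call(rbind, lapply(c(1, -1), function(p) {
    l <- lib[lib$polarity == p, ]
    l[order(-l$rel_intensity), ][1:45, ]
  }))
  mix <- table(top90$class)
  expect_equal(as.integer(mix[["PC"]]), 30L)
  expect_equal(as.integer(mix[["PS"]]), 10L)
  expect_equal(as.integer(mix[["Cer"]]), 10L)
  expect_equal(as.integer(mix[["SHexCer"]]), 8L)
  expect_equal(as.integer(mix[["PE"]]), 8L)
  # no two ions of one polarity share (or neighbour) a 0.05-Da bin
  ax <- mass_axis()
  for (p in c(1, -1)) {
    b <- sort(bin_of(ax, lib$mz[lib$polarity == p]))
    expect_true(all(diff(b) >= 2))
  }
})

test_that("label transfer conserves expected intensity and empties at f=1", {
  inc1 <- default_incorporation(f = 1)
  cfg <- sim_config(seed = 1, incorporation = inc1)
  for (pol in c(1, -1)) {
    ctrl <- simslipid:::arm_expectation(cfg, "control", pol)
    trt <- simslipid:::arm_expectation(cfg, "15N-choline", pol)
    # total expected intensity is conserved under labeling
    expect_equal(sum(trt$cell$intensity), sum(ctrl$cell$intensity),
                 tolerance = 1e-12)
    if (length(trt$source_bins)) {
      src <- trt$cell$intensity[match(trt$source_bins, trt$cell$bin)]
      src[is.na(src)] <- 0
      expect_true(all(src == 0))  # f = 1 moves everything
      lab <- trt$cell$intensity[match(trt$shifted_bins, trt$cell$bin)]
      orig <- ctrl$cell$intensity[match(trt$source_bins, ctrl$cell$bin)]
      expect_equal(sum(lab), sum(orig), tolerance = 1e-12)
    }
  }
  # f = 0 arm has exactly the control expectation
  inc0 <- default_incorporation(f = 0)
  cfg0 <- sim_config(seed = 1, incorporation = inc0)
  expect_equal(simslipid:::arm_expectation(cfg0, "15N-choline", 1)$cell,
               simslipid:::arm_expectation(cfg0, "control", 1)$cell)
})

test_that("generator counts match expectations within Poisson bounds", {
  cfg <- sim_config(seed = 7, bio_cv = 0)   # isolate counting noise
  reps <- lapply(1:6, function(s)
    simulate_roi_spectra(cfg, "control", -1, n_rois = 5, stream = s))
  gt <- attr(reps[[1]], "ground_truth")
  raw <- do.call(rbind, lapply(unlist(reps, recursive = FALSE),
                               function(s) s$raw))
  area <- cfg$roi_pixels
  lam <- area * gt$cell_expectation$intensity
  m <- colMeans(raw[, gt$cell_expectation$bin])
  n <- nrow(raw)
  # 3 sigma band on the mean of n Poisson draws (areas jitter ~10%)
  tol <- 3 * sqrt(lam / n) + 0.11 * lam
  expect_true(all(abs(m - lam) <= tol + 1e-9))
})

test_that("seeded generation is deterministic and streams differ", {
  cfg <- tiny_sim_config(seed = 5)
  a <- render_arm(cfg, "control", 1, image_index = 1)
  b <- render_arm(cfg, "control", 1, image_index = 1)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  c2 <- render_arm(cfg, "control", 1, image_index = 2)
  expect_false(identical(as.matrix(a$counts), as.matrix(c2$counts)))
  cfg2 <- tiny_sim_config(seed = 6)
  d <- render_arm(cfg2, "control", 1, image_index = 1)
  expect_false(identical(as.matrix(a$counts), as.matrix(d$counts)))
})

test_that("a small experiment writes cubes plus a reproducible manifest", {
  cfg <- small_config(seed = 3)
  d1 <- file.path(tempdir(), "exp1"); d2 <- file.path(tempdir(), "exp2")
  m1 <- generate_experiment(cfg, d1, arms = "13C-palmitate",
                            n_control_images = 2, n_treated_images = 1)
  m2 <- generate_experiment(cfg, d2, arms = "13C-palmitate",
                            n_control_images = 2, n_treated_images = 1)
  expect_identical(readLines(m1), readLines(m2))  # byte-identical manifests

  man <- jsonlite::fromJSON(m1)
  expect_equal(man$n_species, nrow(cfg$lipidome))
  expect_equal(nrow(man$lipidome), nrow(cfg$lipidome))
  expect_equal(length(man$files$file), (2 + 1) * 2)

  # geometry and counts survive the imzML round trip
  f <- file.path(d1, man$files$file[[1]])
  img <- read_imzml(f)
  expect_equal(img$nx, cfg$nx)
  expect_equal(img$ny, cfg$ny)
  expect_equal(img$axis$n_bins, cfg$axis$n_bins)
  re <- render_arm(cfg, man$files$arm[[1]],
                   polarity = man$files$polarity[[1]],
                   image_index = man$files$field[[1]])
  expect_equal(as.matrix(img$counts), as.matrix(re$counts))

  # the treated arm's manifest records the shifted bin of the target
  shifted <- man$arms[["13C-palmitate"]]$negative$shifted_bins
  lab_mz <- build_ion_library(data.frame(
    name = "13C-FA 16:0", ions = "-H", explicit_formula = "",
    stringsAsFactors = FALSE))$mz
  expect_equal(shifted, bin_of(cfg$axis, lab_mz))
})

test_that("the pipeline recovers the planted direction on the small fixture", {
  cfg <- small_config(seed = 11)
  ctrl <- simulate_roi_spectra(cfg, "control", -1, n_rois = 20, stream = 1)
  trt <- simulate_roi_spectra(cfg, "13C-palmitate", -1, n_rois = 8,
                              stream = 2)
  gt <- attr(trt, "ground_truth")
  tab <- suppressWarnings(run_turnover(trt, ctrl, top_fraction = 0.3))
  lab_row <- tab[tab$bin %in% gt$shifted_bins, ]
  src_row <- tab[tab$bin %in% gt$source_bins, ]
  expect_equal(lab_row$direction, "increase")
  expect_true(lab_row$significant)
  expect_equal(src_row$direction, "decrease")
  expect_true(src_row$significant)
})
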