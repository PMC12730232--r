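test_that("Mann-Whitney U matches brute-force enumeration (with ties)", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))[c("U", "p")],
               list(U = 0, p = 0.1))
  set.seed(10)
  sizes <- subset(expand.grid(n1 = 2:6, n2 = 2:6), n1 + n2 <= 12)
  for (i in seq_len(nrow(sizes))) {
    n1 <- sizes$n1[i]; n2 <- sizes$n2[i]
    x <- sample(1:4, n1, replace = TRUE)   # coarse values force ties
    y <- sample(1:4, n2, replace = TRUE)
    got <- mann_whitney_u(x, y)
    want <- oracle_mw(x, y)
    expect_equal(got$U, want$U, label = sprintf("U n1=%d n2=%d", n1, n2))
    expect_equal(got$p, want$p, label = sprintf("p n1=%d n2=%d", n1, n2))
    # continuous data too
    x <- rnorm(n1); y <- rnorm(n2)
    got <- mann_whitney_u(x, y); want <- oracle_mw(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p)
  }
})

test_that("Mann-Whitney edge cases and asymptotics behave", {
  expect_equal(mann_whitney_u(rep(2, 4), rep(2, 5))$p, 1)
  big <- mann_whitney_u(rnorm(8) + 100, rnorm(20))
  expect_equal(big$method, "normal approximation")
  expect_equal(big$U, 160)
  expect_lt(big$p, 0.001)

  # agreement with the standard implementation on the asymptotic path
  set.seed(3)
  x <- rnorm(12); y <- rnorm(16, 0.5)
  ours <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  # and on the exact no-ties path
  x <- rnorm(5); y <- rnorm(6)
  expect_equal(mann_whitney_u(x, y)$p,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("U is antisymmetric and p is rank-invariant", {
  set.seed(4)
  for (r in 1:10) {
    x <- sample(1:10, 5, TRUE); y <- sample(1:10, 7, TRUE)
    a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
    expect_equal(a$U + b$U, length(x) * length(y))
    expect_equal(a$p, b$p)
    # monotone transform leaves the test unchanged
    tr <- function(v) exp(v / 2) + 3
    m <- mann_whitney_u(tr(x), tr(y))
    expect_equal(m$U, a$U)
    expect_equal(m$p, a$p)
  }
})

test_that("PCA of spectra behaves on constructed cases", {
  set.seed(6)
  # two clusters separated along one feature: PC1 captures ~everything
  base <- matrix(rnorm(20 * 10, sd = 1e-3), 20, 10)
  base[11:20, 4] <- base[11:20, 4] + 10
  dec <- pca_spectra(base)
  expect_gt(dec$explained[1], 0.99)
  expect_equal(which.max(abs(dec$loadings[, 1])), 4L)

  # identical spectra: zero components
  same <- matrix(rep(1:8, each = 5), 5, 8)
  dec0 <- pca_spectra(same)
  expect_equal(ncol(dec0$scores), 0L)

  # full reconstruction at all components
  x <- matrix(rnorm(6 * 9), 6, 9)
  dec2 <- pca_spectra(x)
  rec <- dec2$scores %*% t(dec2$loadings)
  expect_equal(rec, sweep(x, 2, colMeans(x)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # loadings orthonormal
  expect_equal(crossprod(dec2$loadings), diag(ncol(dec2$loadings)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("discriminant selection finds planted bins and warns when none", {
  set.seed(8)
  mat <- matrix(rnorm(24 * 40), 24, 40)
  groups <- rep(c("a", "b"), each = 12)
  mat[groups == "b", 17] <- mat[groups == "b", 17] + 5
  dec <- pca_spectra(mat)
  sel <- select_discriminant_peaks(dec, groups, top_fraction = 1 / 40)
  expect_equal(as.integer(sel), 17L)

  # identical spectra: zero components, empty selection with warning
  same <- matrix(rep(rnorm(40), each = 24), 24, 40)
  expect_warning(
    sel0 <- select_discriminant_peaks(pca_spectra(same), groups,
                                      top_fraction = 0.1),
    "no variance")
  expect_length(sel0, 0)

  # variance present but orthogonal to the groups: warned, empty
  trend <- outer(1:24, rep(1, 40))          # rank-1: PC1 = a linear trend
  inter <- rep(c("a", "b"), 12)             # interleaved groups: |t| < 1
  expect_warning(
    sel1 <- select_discriminant_peaks(pca_spectra(trend), inter,
                                      top_fraction = 0.1),
    "no component separates")
  expect_length(sel1, 0)
})

test_that("turnover tables call direction, significance and isotope flags", {
  cfg <- sim_config(seed = 42)
  lib <- cfg$lipidome
  arm <- "15N-choline"
  ctrl <- simulate_roi_spectra(cfg, "control", 1, n_rois = 20, stream = 1)
  trt <- simulate_roi_spectra(cfg, arm, 1, n_rois = 8, stream = 2)
  tab <- suppressWarnings(run_turnover(trt, ctrl, library = lib))
  ax <- cfg$axis
  b184 <- bin_of(ax, 184.0733)
  b185 <- bin_of(ax, 184.0733 + SHIFT_15N)
  r184 <- tab[tab$bin == b184, ]
  r185 <- tab[tab$bin == b185, ]
  expect_equal(r184$direction, "decrease")  # unlabeled headgroup depleted
  expect_equal(r185$direction, "increase")  # labeled headgroup appears
  expect_true(r184$significant)
  expect_true(r185$significant)
  expect_true(r185$isotope_shift)           # sits one 15N shift above library
  expect_false(r184$isotope_shift)
  expect_equal(r184$best_name, "PC headgroup")
  expect_true(all(tab$p > 0 & tab$p <= 1))
  expect_true(all(tab$U >= 0 & tab$U <= 8 * 20))
  # direction is consistent with the group means everywhere
  expect_true(all(ifelse(tab$mean_treated > tab$mean_control, "increase",
                         ifelse(tab$mean_treated < tab$mean_control,
                                "decrease", "none")) == tab$direction))
})

test_that("condition comparison joins two arms against a shared control", {
  cfg <- sim_config(seed = 9)
  ctrl_p <- simulate_roi_spectra(cfg, "control", 1, n_rois = 20, stream = 1)
  trt_a <- simulate_roi_spectra(cfg, "15N-choline", 1, n_rois = 8, stream = 2)
  trt_b <- simulate_roi_spectra(cfg, "13C-stearic", 1, n_rois = 8, stream = 3)
  ta <- suppressWarnings(run_turnover(trt_a, ctrl_p))
  tb <- suppressWarnings(run_turnover(trt_b, ctrl_p))
  j <- compare_conditions(ta, tb)
  expect_true(all(c("direction_a", "direction_b", "p_a", "p_b") %in% names(j)))
  expect_equal(nrow(j), length(union(ta$bin, tb$bin)))
  # an arm against itself gives identical columns
  jj <- compare_conditions(ta, ta)
  expect_identical(jj$direction_a, jj$direction_b)
  expect_identical(jj$p_a, jj$p_b)
})
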