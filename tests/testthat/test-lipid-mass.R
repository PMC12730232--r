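test_that("element table is internally consistent", {
  em <- element_masses()
  expect_true(all(em > 0))
  expect_equal(MASS_PROTON, em[["H"]] - MASS_ELECTRON, tolerance = 1e-6)
  expect_equal(monoisotopic_mass(mol_formula(H = 2, O = 1)), MASS_H2O,
               tolerance = 1e-6)
})

test_that("monoisotopic mass is additive and label-aware", {
  f <- parse_formula("C16H32O2")
  expect_equal(monoisotopic_mass(f), 256.2402, tolerance = 1e-4)
  expect_identical(monoisotopic_mass(mol_formula()), 0)
  expect_equal(monoisotopic_mass(f, "c13:1") - monoisotopic_mass(f),
               SHIFT_13C)
  # additivity: mass(A) + mass(B) = mass(A union B)
  a <- parse_formula("C3H5NO2"); b <- parse_formula("C5H15NO4P")
  expect_equal(monoisotopic_mass(a) + monoisotopic_mass(b),
               monoisotopic_mass(simslipid:::formula_add(a, b)))
  expect_error(monoisotopic_mass(mol_formula(Xx = 1)), "unknown element")
  # label cannot exceed the element count
  expect_error(monoisotopic_mass(parse_formula("CH4"), "c13:2"), "exceeds")
  expect_error(monoisotopic_mass(parse_formula("C2H6"), "n15:1"), "exceeds")
})

test_that("shorthand parser handles the printed naming variants", {
  sp <- parse_shorthand("PC 38:2")
  expect_equal(sp$class_code, "PC")
  expect_equal(sp$n_carbons, 38L)
  expect_equal(sp$n_double_bonds, 2L)
  expect_equal(sp$ether_links, 0L)
  expect_null(sp$label)

  sp <- parse_shorthand("[PS 36:1–87-H]−")  # en-dash, unicode minus
  ion <- attr(sp, "ion")
  expect_equal(sp$class_code, "PS")
  expect_equal(ion$adduct, "-H")
  expect_equal(ion$losses, "serine")
  expect_equal(ion$polarity, -1L)

  sp <- parse_shorthand("LPI O-18:2")
  expect_equal(sp$ether_links, 1L)
  expect_equal(sp$n_carbons, 18L)

  sp <- parse_shorthand("¹³C-Cer 34:1;O2")  # superscript 13
  expect_equal(sp$class_code, "Cer")
  expect_equal(sp$extra_oxygens, 0L)   # ;O2 is the sphingolipid baseline
  expect_equal(sp$label, list(type = "c13", k = 1L))

  sp <- parse_shorthand("[DG 34:3+H-H2O]+")
  ion <- attr(sp, "ion")
  expect_true(ion$water_loss)
  expect_equal(ion$adduct, "+H")

  sp <- parse_shorthand("[PC 34:1-TMA+K]+")
  ion <- attr(sp, "ion")
  expect_equal(ion$adduct, "+K")
  expect_equal(ion$losses, "TMA")

  # explicit elemental composition, labeled
  sp <- parse_shorthand("[15N-C5H15PNO4]+")
  expect_equal(sp$label, list(type = "n15", k = 1L))
  expect_equal(attr(sp, "ion")$adduct, "none")

  expect_error(parse_shorthand("XX 34:1"), "unknown lipid class")
  expect_error(parse_shorthand("PC 34-1"), "malformed|cannot parse")
})

test_that("composition rules match the brute-force constructor", {
  cases <- expand.grid(
    class = c("FA", "MG", "DG", "TG", "PA", "PC", "PE", "PG", "PI", "PS",
              "LPA", "LPC", "LPE", "LPG", "LPI", "LPS",
              "Cer", "HexCer", "SHexCer", "CerPE", "SM"),
    n = c(16L, 34L, 38L), d = c(0L, 2L), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    cl <- cases$class[i]; n <- cases$n[i]; d <- cases$d[i]
    sp <- lipid_species(cl, n, d)
    expect_equal(monoisotopic_mass(formula_of(sp)),
                 oracle_species_mass(cl, n, d),
                 tolerance = 1e-9,
                 label = sprintf("%s %d:%d", cl, n, d))
  }
  # ether and oxygen variants
  expect_equal(monoisotopic_mass(formula_of(lipid_species("LPI", 18, 2,
                                                          ether_links = 1))),
               oracle_species_mass("LPI", 18, 2, ether = 1), tolerance = 1e-9)
  expect_equal(monoisotopic_mass(formula_of(lipid_species("Cer", 34, 1,
                                                          extra_oxygens = 2))),
               oracle_species_mass("Cer", 34, 1, extra_oxygens = 2),
               tolerance = 1e-9)
  expect_equal(monoisotopic_mass(formula_of(lipid_species("FA", 18, 3,
                                                          extra_oxygens = 1))),
               oracle_species_mass("FA", 18, 3, extra_oxygens = 1),
               tolerance = 1e-9)
})

test_that("specific formulas come out as expected", {
  expect_equal(format_formula(formula_of(lipid_species("PC", 38, 2))),
               "C46H88NO8P")
  expect_equal(format_formula(formula_of(lipid_species("FA", 16, 0))),
               "C16H32O2")
  expect_equal(format_formula(formula_of(lipid_species("FA", 1, 0))),
               "CH2O2")   # formic acid, smallest class member
  expect_equal(format_formula(formula_of(lipid_species("LPI", 18, 2,
                                                       ether_links = 1))),
               "C27H51O11P")
  expect_error(formula_of(lipid_species("ST", 28, 4)), "no composition rule")
  expect_error(formula_of(lipid_species("CE", 18, 1)), "no composition rule")
})

test_that("ion m/z includes adducts, losses, water and electron terms", {
  pc382 <- formula_of(lipid_species("PC", 38, 2))
  expect_equal(round(ion_mz(pc382, ion_spec("+H")), 2), 814.63)
  ps361 <- formula_of(lipid_species("PS", 36, 1))
  expect_equal(round(ion_mz(ps361, ion_spec("-H", losses = "serine")), 2),
               701.51)
  expect_equal(round(ion_mz("C5H15NO4P", ion_spec("none", polarity = 1)), 2),
               184.07)
  pc341 <- formula_of(lipid_species("PC", 34, 1))
  expect_equal(round(ion_mz(pc341, ion_spec("+K", losses = "TMA")), 2),
               739.47)
  # electron bookkeeping: cation + anion of the same formula differ by 2 e
  f <- parse_formula("C10H20O2")
  plus <- ion_mz(f, ion_spec("none", polarity = 1))
  minus <- ion_mz(f, ion_spec("none", polarity = -1))
  expect_equal(minus - plus, 2 * MASS_ELECTRON, tolerance = 1e-9)
  # polarity consistency enforced
  expect_error(ion_spec("-H", polarity = 1), "inconsistent")
  expect_error(ion_spec("+Na", polarity = -1), "inconsistent")
})

test_that("label shifts are exact multiples of the isotope deltas", {
  for (sp_name in c("PC 34:1", "FA 18:0", "PS 40:6")) {
    base <- parse_annotated_ion(paste0("[", sp_name, "+H]+"))$mz
    for (k in 1:2) {
      lab <- parse_annotated_ion(sprintf("[13C%d-%s+H]+",
                                         k, sp_name))$mz
      expect_equal(lab - base, k * SHIFT_13C, tolerance = 1e-12)
    }
    if (sp_name != "FA 18:0") {  # 15N needs a nitrogen atom
      lab <- parse_annotated_ion(paste0("[15N-", sp_name, "+H]+"))$mz
      expect_equal(lab - base, SHIFT_15N, tolerance = 1e-12)
    }
  }
  # labeling a nitrogen-free species with 15N is rejected
  expect_error(parse_annotated_ion("[15N-FA 18:0+H]+"), "exceeds")
})

test_that("ppm errors are signed and definitional", {
  expect_equal(ppm_error(800, 800), 0)
  expect_equal(ppm_error(800.08, 800), 100)
  expect_equal(ppm_error(184.07, 184.0733), -17.9, tolerance = 0.05)
  expect_error(ppm_error(100, -1))
})

test_that("annotation finds, ranks and flags candidates deterministically", {
  lib <- default_lipidome()
  res <- annotate(c(814.63, 150.00), lib, tol_ppm = 100, polarity = 1)
  expect_true(res[[1]]$assigned)
  expect_equal(res[[1]]$candidates$ion_form[1], "[PC 38:2+H]+")
  expect_false(res[[2]]$assigned)
  expect_equal(nrow(res[[2]]$candidates), 0L)

  # candidates sorted by |ppm|, invariant to library row order
  set.seed(42)
  shuffled <- lib[sample(nrow(lib)), ]
  res2 <- annotate(c(814.63, 150.00), shuffled, tol_ppm = 100, polarity = 1)
  expect_identical(res[[1]]$candidates, res2[[1]]$candidates)

  # peak order independence
  res3 <- annotate(c(150.00, 814.63), lib, tol_ppm = 100, polarity = 1)
  expect_identical(res3[[2]]$candidates, res[[1]]$candidates)

  # labeled library entries are matched too
  lab_lib <- build_ion_library(data.frame(
    name = "13C-PS 44:12", ions = "-H", explicit_formula = "",
    stringsAsFactors = FALSE))
  hit <- annotate(879.50, lab_lib, tol_ppm = 100, polarity = -1)[[1]]
  expect_true(hit$assigned)
  expect_equal(hit$candidates$name[1], "13C-PS 44:12")
})

test_that("reference assignment audit passes with only the known exceptions", {
  res <- check_reference_assignments()
  expect_true(all(res$parseable))
  expect_gte(attr(res, "agreement"), 0.9)
  flagged <- res$ion[res$flagged]
  expect_setequal(flagged, c("[PE 20:0+Na]+", "[LPC 16:0+K]+"))
  # the flagged pair sit ~1 Da above the calculus, not random noise
  expect_equal(res$reported_mz[res$flagged] - res$computed_mz[res$flagged],
               c(1, 1), tolerance = 0.02)
})
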