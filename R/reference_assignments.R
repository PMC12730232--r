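#' Curated reference lipid assignments
#'
#' Reported single-cell ToF-SIMS assignments of neuronal plasma-membrane
#' lipids (shorthand ion form plus reported m/z at the 2-decimal convention;
#' a few values are reported at 1 decimal). The sterol entry carries an
#' explicit formula because the `ST` shorthand has no composition rule.
#' This table is the input to [check_reference_assignments()]; a few
#' reported values are known to disagree with the standard calculus by
#' about 1 Da and are expected to come back flagged, not forced to match.
#'
#' @return Data frame with columns `ion`, `reported_mz`, `explicit_formula`.
#' @export
reference_assignments <- function() {
  rows <- list(
    # abundance profile (positive / negative mode top peaks)
    list("[PC 38:2+H]+",           814.63, NA),
    list("[PC 36:2+Na]+",          808.58, NA),
    list("[PC 38:4+Na]+",          832.58, NA),
    list("[PS 36:1-87-H]-",        701.51, NA),
    list("[ST 28:4;O6-H]-",        473.29, "C28H42O6"),
    list("[FA 16:0-H]-",           255.23, NA),
    list("[C5H15PNO4]+",           184.07, NA),
    list("[FA 18:0-H]-",           283.26, NA),
    # headgroup precursor comparisons (choline / ethanolamine)
    list("[15N-C5H15PNO4]+",       185.07, NA),
    list("[PE 20:0+Na]+",          547.32, NA),   # known ~1 Da exception
    list("[HexCer 32:2;O3+Na]+",   708.50, NA),
    list("[Cer 38:0;O-H]-",        578.59, NA),
    list("[Cer 34:1;O4+H]+",       570.50, NA),
    list("[DG 34:3+H-H2O]+",       573.49, NA),
    list("[PS 20:0;O-H]-",         582.30, NA),
    list("[PC 32:1+H]+",           732.55, NA),
    list("[PA 24:2;O3-H]-",        579.29, NA),
    list("[SHexCer 42:2;O2-H]-",   888.62, NA),
    list("[PS 40:6-H]-",           834.53, NA),
    list("[13C2-LPE 26:6-H]-",     582.34, NA),
    list("[MG 20:5+K]+",           415.22, NA),
    list("[LPA 20:4-H]-",          457.24, NA),
    list("[LPE 18:3-H]-",          474.26, NA),
    list("[15N-PC 32:0+K]+",       773.53, NA),
    list("[15N-PC 32:1+K]+",       771.51, NA),
    list("[15N-PC 34:1+K]+",       799.54, NA),
    list("[13C2-PE O-38:5-H]-",    752.54, NA),
    list("[PI 38:3-H]-",           887.57, NA),
    list("[PI 38:4-H]-",           885.55, NA),
    # fatty-acid precursor comparisons (unsaturation)
    list("[13C-PE 34:3+H]+",       715.51, NA),
    list("[13C-PG 34:0+Na]+",      774.53, NA),
    list("[13C-FA 18:3;O-H]-",     294.21, NA),
    list("[13C-PS 44:2-H]-",       899.65, NA),
    list("[13C-FA 16:0-H]-",       256.23, NA),
    list("[13C-LPA 16:1-H]-",      408.22, NA),
    list("[13C-PS 44:12-H]-",      879.50, NA),
    list("[PS 44:8-H]-",           886.56, NA),
    # fatty-acid precursor comparisons (saturation, chain length)
    list("[13C-C21H40O6P]-",       420.26, NA),
    list("[13C-LPI O-18:2-H]-",    582.31, NA),
    list("[13C-LPI 18:0-H]-",      600.32, NA),
    list("[13C-FA 18:0-H]-",       284.26, NA),
    list("[13C-PC 30:1+K]+",       743.48, NA),
    list("[13C-PI 38:8-H]-",       878.49, NA),
    list("[13C-PI 38:7-H]-",       880.50, NA),
    list("[13C-PI 38:2-H]-",       890.58, NA),
    list("[13C-PS 44:0-H]-",       903.69, NA),
    list("[FA 16:1-H]-",           253.22, NA),
    list("[13C-CerPE 32:2;O2+Na]+", 654.46, NA),
    list("[FA 18:1-H]-",           281.25, NA),
    list("[PI 38:5-H]-",           883.53, NA),
    list("[13C-PC 34:1+K]+",       799.54, NA),
    list("[13C-FA 18:1-H]-",       282.25, NA),
    list("[13C-Cer 34:1;O2+K]+",   577.48, NA),
    list("[13C-PS 44:13-H]-",      877.48, NA),
    list("[13C-PS 44:14-H]-",      875.47, NA),
    list("[13C-FA 20:4-H]-",       304.23, NA),
    list("[FA 20:4-H]-",           303.23, NA),
    list("[LPI O-18:2-H]-",        581.31, NA),
    list("[13C-PI 38:4-H]-",       886.55, NA),
    list("[13C-PS 44:8-H]-",       887.56, NA),
    list("[13C-Cer 38:2;O2+H]+",   593.57, NA),
    list("[13C-PS 42:7-H]-",       861.54, NA),
    list("[PC 16:4+H]+",           502.26, NA),
    list("[HexCer 30:2;O2+K]+",    680.45, NA),
    list("[PC 34:1-TMA+K]+",       739.47, NA),
    list("[PC 34:1+H]+",           760.59, NA),
    list("[13C-Cer 38:1;O+Na]+",   601.57, NA),
    list("[13C-CerPE 40:4;O2+Na]+", 762.56, NA),
    list("[LPC 16:0+K]+",          535.30, NA),  # known ~1 Da exception
    list("[13C-PS 36:0-H]-",       791.56, NA)
  )
  data.frame(
    ion = vapply(rows, `[[`, character(1), 1L),
    reported_mz = vapply(rows, `[[`, numeric(1), 2L),
    explicit_formula = vapply(rows, function(r)
      if (is.na(r[[3]])) NA_character_ else r[[3]], character(1)),
    stringsAsFactors = FALSE
  )
}
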