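#' Ion specification: adduct, water loss, neutral losses, polarity
#'
#' @param adduct One of `"+H"`, `"+Na"`, `"+K"`, `"-H"`, or `"none"` for
#'   species whose formula is already the ion (e.g. the phosphocholine
#'   headgroup cation).
#' @param water_loss `TRUE` for `[M+H-H2O]+`-type ions.
#' @param losses Character vector of named neutral losses; currently
#'   `"serine"` (C3H5NO2, the 87 Da loss from PS) and `"TMA"`
#'   (trimethylamine, C3H9N, lost from PC).
#' @param polarity `+1` or `-1`; must be consistent with the adduct
#'   (deprotonation implies negative, cationization positive). Required when
#'   `adduct = "none"`.
#' @return An `ion_spec` object (singly charged by construction).
#' @export
ion_spec <- function(adduct = c("+H", "+Na", "+K", "-H", "none"),
                     water_loss = FALSE, losses = character(),
                     polarity = NULL) {
  adduct <- match.arg(adduct)
  implied <- switch(adduct, "+H" = 1L, "+Na" = 1L, "+K" = 1L, "-H" = -1L,
                    "none" = NULL)
  if (is.null(implied)) {
    if (is.null(polarity)) stop("polarity required when adduct = 'none'")
    implied <- as.integer(sign(polarity))
  } else if (!is.null(polarity) && sign(polarity) != implied) {
    stop("polarity ", polarity, " inconsistent with adduct ", adduct)
  }
  known <- names(neutral_loss_formulas())
  if (length(losses) && !all(losses %in% known))
    stop("unknown neutral loss: ", paste(setdiff(losses, known), collapse = ", "))
  structure(list(adduct = adduct, water_loss = isTRUE(water_loss),
                 losses = losses, polarity = implied),
            class = "ion_spec")
}

#' @export
print.ion_spec <- function(x, ...) {
  cat("<ion_spec>", ion_suffix(x), if (x$polarity > 0) "+" else "-", "\n")
  invisible(x)
}

# Bracket-notation suffix for an ion spec, e.g. "-87-H" or "-TMA+K".
ion_suffix <- function(is) {
  loss_tok <- c(serine = "-87", TMA = "-TMA")
  paste0(paste0(loss_tok[is$losses], collapse = ""),
         if (is$adduct != "none") is$adduct else "",
         if (is$water_loss) "-H2O" else "")
}

#' m/z of a singly charged lipid ion
#'
#' `mz = M + adduct - water - losses -/+ electron (+ label shift)`: the
#' neutral monoisotopic mass plus the adduct atom (H, Na or K; minus H for
#' deprotonation), minus 18.010565 Da if a water loss is flagged, minus the
#' named neutral-loss masses, with the electron mass subtracted for cations
#' and added for anions. The electron term never changes an assignment at
#' a 100 ppm tolerance but keeps the calculus exact.
#'
#' @param formula Neutral `mol_formula` (or string).
#' @param ion An `ion_spec`.
#' @param label Optional isotope label (`"c13:k"` / `"n15:k"`).
#' @return m/z in Da per unit charge.
#' @export
#' @examples
#' ion_mz(formula_of(lipid_species("PC", 38, 2)), ion_spec("+H"))  # 814.632
ion_mz <- function(formula, ion, label = NULL) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(ion, "ion_spec"))
  em <- element_masses()
  m <- monoisotopic_mass(formula, label)
  m <- m + switch(ion$adduct,
    "+H"   = MASS_PROTON + MASS_ELECTRON,  # a hydrogen atom; electron handled below
    "+Na"  = em[["Na"]],
    "+K"   = em[["K"]],
    "-H"   = -(MASS_PROTON + MASS_ELECTRON),
    "none" = 0
  )
  if (ion$water_loss) m <- m - MASS_H2O
  for (l in ion$losses)
    m <- m - monoisotopic_mass(do.call(mol_formula, as.list(neutral_loss_formulas()[[l]])))
  m - ion$polarity * MASS_ELECTRON
}

#' A theoretical ion: species + ion form + computed m/z
#'
#' @param species A `lipid_species`.
#' @param ion An `ion_spec`.
#' @return A `theoretical_ion` with fields `species`, `ion`, `formula`
#'   (the ion's formula after adduct and losses) and `mz`.
#' @export
theoretical_ion <- function(species, ion) {
  neutral <- formula_of(species)
  f <- neutral
  f <- switch(ion$adduct,
    "+H"   = formula_add(f, mol_formula(H = 1)),
    "+Na"  = formula_add(f, mol_formula(Na = 1)),
    "+K"   = formula_add(f, mol_formula(K = 1)),
    "-H"   = formula_subtract(f, mol_formula(H = 1)),
    "none" = f
  )
  if (ion$water_loss) f <- formula_subtract(f, mol_formula(H = 2, O = 1))
  for (l in ion$losses)
    f <- formula_subtract(f, do.call(mol_formula, as.list(neutral_loss_formulas()[[l]])))
  # label atoms must survive the losses (losses are headgroup fragments,
  # labels sit in chains/headgroups as configured; validate against the ion)
  structure(list(
    species = species,
    ion = ion,
    formula = f,
    mz = ion_mz(neutral, ion, species$label)
  ), class = "theoretical_ion")
}

#' @export
print.theoretical_ion <- function(x, ...) {
  cat(sprintf("<theoretical_ion> %s  m/z %.4f\n", ion_name(x), x$mz))
  invisible(x)
}

#' Bracketed display name of a theoretical ion, e.g. `"[PC 38:2+H]+"`
#' @param ti A `theoretical_ion`.
#' @export
ion_name <- function(ti) {
  paste0("[", ti$species$name, ion_suffix(ti$ion), "]",
         if (ti$ion$polarity > 0) "+" else "-")
}

#' Signed parts-per-million mass error
#'
#' `1e6 * (observed - theoretical) / theoretical`.
#'
#' @param observed,theoretical m/z values; `theoretical` must be positive.
#' @return Signed ppm error (vectorized).
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  1e6 * (observed - theoretical) / theoretical
}
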