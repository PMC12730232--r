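#' Supported lipid class codes
#'
#' Class codes recognized by the shorthand parser. Composition rules exist
#' for all of them except `ST` and `CE`, which can only be annotated through
#' an explicit user-supplied formula.
#'
#' @export
lipid_classes <- function() {
  c("FA", "MG", "DG", "TG", "PA", "PC", "PE", "PG", "PI", "PS",
    "LPA", "LPC", "LPE", "LPG", "LPI", "LPS",
    "Cer", "HexCer", "SHexCer", "CerPE", "SM", "CE", "ST")
}

# Composition rules: the neutral species of class X with n total chain
# carbons and d double bonds has formula
#   C(n+dc) H(2n-2d+dh) N(nN) O(nO + extra_oxygens) P(nP) S(nS).
# Sphingolipid classes (sphingo = TRUE) are written against the ";O2"
# shorthand baseline, i.e. their nO is the oxygen count of the ";O2" form
# and a ";O" suffix contributes extra_oxygens = -1.
# Each ether linkage ("O-" prefix) replaces an ester bond: -1 O, +2 H.
class_rules <- function() {
  list(
    FA  = list(dc = 0L, dh = 0L,  N = 0L, O = 2L,  P = 0L, S = 0L, sphingo = FALSE),
    MG  = list(dc = 3L, dh = 6L,  N = 0L, O = 4L,  P = 0L, S = 0L, sphingo = FALSE),
    DG  = list(dc = 3L, dh = 4L,  N = 0L, O = 5L,  P = 0L, S = 0L, sphingo = FALSE),
    TG  = list(dc = 3L, dh = 2L,  N = 0L, O = 6L,  P = 0L, S = 0L, sphingo = FALSE),
    PA  = list(dc = 3L, dh = 5L,  N = 0L, O = 8L,  P = 1L, S = 0L, sphingo = FALSE),
    PC  = list(dc = 8L, dh = 16L, N = 1L, O = 8L,  P = 1L, S = 0L, sphingo = FALSE),
    PE  = list(dc = 5L, dh = 10L, N = 1L, O = 8L,  P = 1L, S = 0L, sphingo = FALSE),
    PS  = list(dc = 6L, dh = 10L, N = 1L, O = 10L, P = 1L, S = 0L, sphingo = FALSE),
    PG  = list(dc = 6L, dh = 11L, N = 0L, O = 10L, P = 1L, S = 0L, sphingo = FALSE),
    PI  = list(dc = 9L, dh = 15L, N = 0L, O = 13L, P = 1L, S = 0L, sphingo = FALSE),
    LPA = list(dc = 3L, dh = 7L,  N = 0L, O = 7L,  P = 1L, S = 0L, sphingo = FALSE),
    LPC = list(dc = 8L, dh = 18L, N = 1L, O = 7L,  P = 1L, S = 0L, sphingo = FALSE),
    LPE = list(dc = 5L, dh = 12L, N = 1L, O = 7L,  P = 1L, S = 0L, sphingo = FALSE),
    LPG = list(dc = 6L, dh = 13L, N = 0L, O = 9L,  P = 1L, S = 0L, sphingo = FALSE),
    LPI = list(dc = 9L, dh = 17L, N = 0L, O = 12L, P = 1L, S = 0L, sphingo = FALSE),
    LPS = list(dc = 6L, dh = 12L, N = 1L, O = 9L,  P = 1L, S = 0L, sphingo = FALSE),
    Cer     = list(dc = 0L, dh = 1L,  N = 1L, O = 3L,  P = 0L, S = 0L, sphingo = TRUE),
    HexCer  = list(dc = 6L, dh = 11L, N = 1L, O = 8L,  P = 0L, S = 0L, sphingo = TRUE),
    SHexCer = list(dc = 6L, dh = 11L, N = 1L, O = 11L, P = 0L, S = 1L, sphingo = TRUE),
    CerPE   = list(dc = 2L, dh = 7L,  N = 2L, O = 6L,  P = 1L, S = 0L, sphingo = TRUE),
    SM      = list(dc = 5L, dh = 13L, N = 2L, O = 6L,  P = 1L, S = 0L, sphingo = TRUE)
  )
}

# Oxygen-suffix baseline per class: sphingolipids are named against ";O2".
class_oxygen_baseline <- function(class_code) {
  rules <- class_rules()
  if (class_code %in% names(rules) && rules[[class_code]]$sphingo) 2L else 0L
}

#' Construct a lipid species
#'
#' @param class_code One of [lipid_classes()], or `"formula"` for a species
#'   defined only by an explicit elemental composition.
#' @param n_carbons Total acyl/chain carbons.
#' @param n_double_bonds Number of C=C double bonds.
#' @param extra_oxygens Oxygen count of the `";Ok"` suffix relative to the
#'   class baseline (sphingolipid classes are written against `";O2"`, so
#'   `"Cer 34:1;O2"` has `extra_oxygens = 0` and `";O"` gives `-1`).
#' @param ether_links Number of `"O-"` ether linkages (0, 1 or 2).
#' @param label `NULL` or a label string `"c13:k"` / `"n15:k"`.
#' @param explicit_formula Optional `mol_formula` (or string) overriding the
#'   class composition rule; required for classes `ST` and `CE`.
#' @param name Optional display name; defaults to the shorthand.
#' @return A `lipid_species` object.
#' @export
#' @examples
#' lipid_species("PC", 38, 2)
#' lipid_species("Cer", 34, 1)                     # "Cer 34:1;O2"
#' lipid_species("LPI", 18, 2, ether_links = 1)    # "LPI O-18:2"
lipid_species <- function(class_code, n_carbons, n_double_bonds,
                          extra_oxygens = 0L, ether_links = 0L,
                          label = NULL, explicit_formula = NULL,
                          name = NULL) {
  if (!is.null(explicit_formula) && is.character(explicit_formula))
    explicit_formula <- parse_formula(explicit_formula)
  if (class_code != "formula" && !class_code %in% lipid_classes())
    stop("unknown lipid class code: '", class_code, "'")
  if (class_code != "formula") {
    stopifnot(n_carbons >= 1, n_double_bonds >= 0, ether_links %in% 0:2)
  }
  lab <- parse_label(label)
  sp <- structure(list(
    class_code = class_code,
    n_carbons = as.integer(n_carbons),
    n_double_bonds = as.integer(n_double_bonds),
    extra_oxygens = as.integer(extra_oxygens),
    ether_links = as.integer(ether_links),
    label = lab,
    explicit_formula = explicit_formula,
    name = name
  ), class = "lipid_species")
  if (is.null(sp$name)) sp$name <- species_name(sp)
  sp
}

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species> ", x$name, "\n", sep = "")
  invisible(x)
}

#' Shorthand name of a species
#' @param sp A `lipid_species`.
#' @return Shorthand string, e.g. `"13C-Cer 34:1;O2"`.
#' @export
species_name <- function(sp) {
  if (sp$class_code == "formula")
    return(format_formula(sp$explicit_formula))
  base <- class_oxygen_baseline(sp$class_code)
  k <- sp$extra_oxygens + base
  suffix <- if (k > 0) paste0(";O", if (k > 1) k else "") else ""
  lab <- if (!is.null(sp$label)) {
    paste0(if (sp$label$type == "c13") "13C" else "15N",
           if (sp$label$k > 1) sp$label$k else "", "-")
  } else ""
  paste0(lab, sp$class_code, " ", strrep("O-", sp$ether_links),
         sp$n_carbons, ":", sp$n_double_bonds, suffix)
}

#' Molecular formula of a lipid species from its class composition rule
#'
#' Applies the per-class rule `C(n+dc) H(2n-2d+dh) N O P S`, adds
#' `extra_oxygens`, and applies `-O +2H` per ether linkage. Species with an
#' `explicit_formula` return it unchanged. Classes `ST` and `CE` have no
#' composition rule (their shorthand hides too much structure) and error
#' unless an explicit formula was supplied.
#'
#' @param sp A `lipid_species`.
#' @return A `mol_formula` of the neutral species.
#' @export
#' @examples
#' format_formula(formula_of(lipid_species("PC", 38, 2)))  # "C46H88NO8P"
formula_of <- function(sp) {
  stopifnot(inherits(sp, "lipid_species"))
  if (!is.null(sp$explicit_formula)) return(sp$explicit_formula)
  rules <- class_rules()
  if (!sp$class_code %in% names(rules))
    stop("no composition rule for class '", sp$class_code,
         "'; supply an explicit formula")
  r <- rules[[sp$class_code]]
  n <- sp$n_carbons; d <- sp$n_double_bonds
  counts <- c(
    C = n + r$dc,
    H = 2L * n - 2L * d + r$dh + 2L * sp$ether_links,
    N = r$N,
    O = r$O + sp$extra_oxygens - sp$ether_links,
    P = r$P,
    S = r$S
  )
  if (counts[["H"]] < 0 || counts[["O"]] < 0)
    stop("composition rule gives negative counts for ", species_name(sp))
  do.call(mol_formula, as.list(counts))
}

#' Monoisotopic mass of a species (label shift included)
#' @param sp A `lipid_species`.
#' @return Mass in Da.
#' @export
species_mass <- function(sp) {
  monoisotopic_mass(formula_of(sp), sp$label)
}
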