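#' Parse lipid shorthand, optionally with a bracketed ion form
#'
#' Grammar (after typographic normalization):
#' `[<label>-]<CLASS> [O-]<n>:<d>[;O<k>]`, optionally wrapped as
#' `[<name><ion terms>]<sign>` where ion terms are `+H`, `+Na`, `+K`, `-H`,
#' `-H2O`, `-87` (serine loss) and `-TMA`. Superscript isotope digits,
#' caret/underscore markup, en-dashes and the Unicode minus are normalized,
#' so `"[13C-Cer 34:1;O2+K]+"` and its typeset variants parse identically.
#' A bare elemental composition in brackets (e.g. `"[C5H15PNO4]+"`) yields
#' an explicit-formula species.
#'
#' @param text Shorthand string, e.g. `"PC 38:2"` or `"[PS 36:1-87-H]-"`.
#' @return A `lipid_species`; for bracketed forms the matching `ion_spec` is
#'   attached as attribute `"ion"` (see [parse_annotated_ion()]).
#' @export
#' @examples
#' parse_shorthand("PC 38:2")
#' attr(parse_shorthand("[PS 36:1-87-H]-"), "ion")
parse_shorthand <- function(text) {
  s <- normalize_shorthand(text)
  ion <- NULL
  sign <- NULL
  m <- regmatches(s, regexec("^\\[(.*)\\]([+-])?$", s))[[1]]
  if (length(m)) {
    s <- m[2]
    if (nzchar(m[3])) sign <- if (m[3] == "+") 1L else -1L
  }

  # strip trailing ion tokens
  adduct <- NULL; water <- FALSE; losses <- character()
  repeat {
    tk <- regmatches(s, regexec("([+-](?:H2O|Na|K|H|TMA|87))$", s))[[1]]
    if (!length(tk)) break
    tok <- tk[2]
    s <- substr(s, 1, nchar(s) - nchar(tok))
    if (tok == "-H2O") water <- TRUE
    else if (tok == "-87") losses <- c("serine", losses)
    else if (tok == "-TMA") losses <- c("TMA", losses)
    else if (tok %in% c("+H", "+Na", "+K")) {
      if (!is.null(adduct)) stop("multiple adducts in '", text, "'")
      adduct <- tok
    } else if (tok == "-H") {
      if (!is.null(adduct)) stop("multiple adducts in '", text, "'")
      adduct <- "-H"
    }
  }
  had_ion_terms <- !is.null(adduct) || water || length(losses) > 0

  # label prefix
  label <- NULL
  lm <- regmatches(s, regexec("^(13C|15N)([0-9]*)-(.*)$", s))[[1]]
  if (length(lm)) {
    k <- if (nzchar(lm[3])) as.integer(lm[3]) else 1L
    label <- list(type = if (lm[2] == "13C") "c13" else "n15", k = k)
    s <- lm[4]
  }

  s <- trimws(s)
  sp <-
    if (grepl("^[A-Z][A-Za-z]*( |$)", s) &&
        grepl(" ", s)) {
      parse_species_core(s, label, text)
    } else if (grepl("^[A-Z][A-Za-z0-9]*$", s) && grepl("[0-9]", s)) {
      # explicit elemental composition, e.g. C5H15PNO4
      lipid_species("formula", 0, 0, explicit_formula = parse_formula(s),
                    label = if (is.null(label)) NULL else
                      paste0(label$type, ":", label$k))
    } else {
      stop("cannot parse lipid shorthand: '", text, "'")
    }

  if (is.null(sign) && !had_ion_terms) return(sp)
  if (is.null(adduct)) {
    adduct <- "none"
    if (is.null(sign)) stop("ion form without adduct or charge sign: '", text, "'")
  }
  is <- ion_spec(adduct, water_loss = water, losses = losses, polarity = sign)
  if (!is.null(sign) && is$polarity != sign)
    stop("charge sign inconsistent with adduct in '", text, "'")
  attr(sp, "ion") <- is
  sp
}

parse_species_core <- function(s, label, orig) {
  m <- regmatches(s, regexec(
    "^([A-Z][A-Za-z]*) ((?:O-)*)([0-9]+):([0-9]+)(?:;O([0-9]*))?$", s))[[1]]
  if (!length(m))
    stop("malformed lipid shorthand (expected 'CLASS n:d'): '", orig, "'")
  cls <- m[2]
  if (!cls %in% lipid_classes())
    stop("unknown lipid class code: '", cls, "' in '", orig, "'")
  ether <- nchar(m[3]) %/% 2L
  n <- as.integer(m[4]); d <- as.integer(m[5])
  k_suffix <- if (is.na(m[6]) || identical(m[6], "")) {
    if (grepl(";O", s, fixed = TRUE)) 1L else NA_integer_
  } else as.integer(m[6])
  base <- class_oxygen_baseline(cls)
  extra <- if (is.na(k_suffix)) 0L else k_suffix - base
  lipid_species(cls, n, d, extra_oxygens = extra, ether_links = ether,
                label = if (is.null(label)) NULL else
                  paste0(label$type, ":", label$k))
}

# Map typeset variants onto the plain grammar: superscript digits, ^..^ and
# _.._ markup, en/em dashes, Unicode minus, comma-for-semicolon in ";O",
# and stray spaces inside class names ("SHex Cer").
normalize_shorthand <- function(text) {
  s <- text
  sup <- c("¹" = "1", "²" = "2", "³" = "3", "⁰" = "0",
           "⁴" = "4", "⁵" = "5", "⁶" = "6", "⁷" = "7",
           "⁸" = "8", "⁹" = "9")
  for (k in names(sup)) s <- gsub(k, sup[[k]], s, fixed = TRUE)
  s <- gsub("[\\^_]", "", s, perl = TRUE)
  s <- gsub("[‒–—−]", "-", s, perl = TRUE)
  s <- gsub(",O", ";O", s, fixed = TRUE)
  s <- gsub("SHex Cer", "SHexCer", s, fixed = TRUE)
  s <- gsub("Hex Cer", "HexCer", s, fixed = TRUE)
  trimws(s)
}

#' Parse a bracketed assignment and build its theoretical ion
#'
#' Convenience wrapper: parses, applies the class composition rule (or an
#' explicit formula) and returns the `theoretical_ion` with computed m/z.
#'
#' @param text Bracketed shorthand, e.g. `"[PC 38:2+H]+"`.
#' @param explicit_formula Optional formula string for rule-less classes.
#' @return A `theoretical_ion`.
#' @export
parse_annotated_ion <- function(text, explicit_formula = NULL) {
  sp <- parse_shorthand(text)
  ion <- attr(sp, "ion")
  if (is.null(ion)) stop("no ion form in '", text, "'")
  if (!is.null(explicit_formula))
    sp$explicit_formula <- parse_formula(explicit_formula)
  theoretical_ion(sp, ion)
}
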