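#' Molecular formulas as named integer count vectors
#'
#' A molecular formula is represented as a named integer vector mapping
#' element symbols to non-negative counts, with class `mol_formula`.
#' The empty formula has mass 0.
#'
#' @param ... Element counts, e.g. `mol_formula(C = 16, H = 32, O = 2)`.
#' @return A `mol_formula` object.
#' @export
#' @examples
#' mol_formula(C = 16, H = 32, O = 2)
mol_formula <- function(...) {
  x <- c(...)
  if (is.null(x)) x <- integer(0)
  counts <- as.integer(round(x))
  names(counts) <- names(x)
  if (length(counts) && (is.null(names(counts)) || any(!nzchar(names(counts)))))
    stop("all formula entries must be named by element symbol")
  if (any(counts < 0))
    stop("negative element count in formula: ",
         paste(names(counts)[counts < 0], collapse = ", "))
  counts <- counts[counts > 0]
  if (length(counts)) counts <- counts[order(names(counts))]
  structure(counts, class = "mol_formula")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat(format_formula(x), "\n")
  invisible(x)
}

#' Format a formula in Hill-like order (C, H, then alphabetical)
#' @param f A `mol_formula`.
#' @return A string such as `"C46H88NO8P"`.
#' @export
format_formula <- function(f) {
  if (!length(f)) return("")
  els <- names(f)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    paste0(e, if (f[[e]] > 1L) f[[e]] else "")
  }, character(1)), collapse = "")
}

#' Parse a chemical formula string such as "C46H88NO8P"
#'
#' Single- and two-letter element symbols with optional counts. Used for
#' explicit ion compositions printed in assignment lists (fragments, sterols)
#' that have no lipid-class composition rule.
#'
#' @param text Formula string.
#' @return A `mol_formula`.
#' @export
parse_formula <- function(text) {
  text <- gsub("[\\s_]", "", text, perl = TRUE)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(text))
    stop("cannot parse formula: '", text, "'")
  counts <- integer(0)
  for (tk in toks) {
    el <- sub("[0-9]*$", "", tk)
    k <- sub("^[A-Za-z]+", "", tk)
    k <- if (nzchar(k)) as.integer(k) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + k
  }
  do.call(mol_formula, as.list(counts))
}

# Elementwise sum / difference of formulas; difference errors on negatives.
formula_add <- function(a, b) {
  els <- union(names(a), names(b))
  out <- vapply(els, function(e) {
    (if (e %in% names(a)) a[[e]] else 0L) + (if (e %in% names(b)) b[[e]] else 0L)
  }, integer(1))
  do.call(mol_formula, as.list(out))
}

formula_subtract <- function(a, b) {
  els <- union(names(a), names(b))
  out <- vapply(els, function(e) {
    (if (e %in% names(a)) a[[e]] else 0L) - (if (e %in% names(b)) b[[e]] else 0L)
  }, integer(1))
  if (any(out < 0))
    stop("formula subtraction would go negative for: ",
         paste(els[out < 0], collapse = ", "))
  do.call(mol_formula, as.list(out))
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element counts times monoisotopic masses, plus the isotope shift
#' for a stable-isotope label: `k` times 1.0033548 Da for `c13:k`,
#' `k` times 0.9970349 Da for `n15:k`.
#'
#' @param formula A `mol_formula` (or string parsed with [parse_formula()]).
#' @param label `NULL`, a string `"c13:k"`/`"n15:k"`, or a list with
#'   elements `type` (`"c13"` or `"n15"`) and `k`.
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass(parse_formula("C16H32O2"))            # 256.2402
#' monoisotopic_mass(parse_formula("C16H32O2"), "c13:1")   # +1.0033548
monoisotopic_mass <- function(formula, label = NULL) {
  if (is.character(formula)) formula <- parse_formula(formula)
  em <- element_masses()
  unknown <- setdiff(names(formula), names(em))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  mass <- if (length(formula)) sum(as.numeric(formula) * em[names(formula)]) else 0
  mass + label_shift(label, formula)
}

# Parse/validate a label spec and return its total mass shift.
# Validates that the labeled atom count does not exceed the element count.
label_shift <- function(label, formula = NULL) {
  lab <- parse_label(label)
  if (is.null(lab)) return(0)
  if (!is.null(formula)) {
    el <- if (lab$type == "c13") "C" else "N"
    have <- if (el %in% names(formula)) formula[[el]] else 0L
    if (lab$k > have)
      stop("label ", lab$type, ":", lab$k, " exceeds ", el,
           " count (", have, ") in formula")
  }
  lab$k * if (lab$type == "c13") SHIFT_13C else SHIFT_15N
}

parse_label <- function(label) {
  if (is.null(label) || (is.character(label) && (!nzchar(label) || label == "none")))
    return(NULL)
  if (is.list(label)) {
    stopifnot(label$type %in% c("c13", "n15"), label$k >= 1)
    return(list(type = label$type, k = as.integer(label$k)))
  }
  m <- regmatches(label, regexec("^(c13|n15):([0-9]+)$", label))[[1]]
  if (length(m) != 3) stop("malformed label: '", label, "'")
  list(type = m[2], k = as.integer(m[3]))
}
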