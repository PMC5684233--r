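## Molecular formulas over a fixed metabolomics element alphabet.
##
## A formula is a plain named integer vector over formulaElements() in fixed
## order. Subtraction of a neutral loss may yield negative counts; such a
## formula is "invalid" but is kept as a value (isValidFormula() tests it)
## rather than clamped or rejected, because chemical invalidity is exactly
## the signal the tree re-rooting decoy uses to decide what to re-graft.

.ELEMENTS <- c("C", "H", "N", "O", "P", "S", "F", "Cl", "Br", "I")

## monoisotopic masses, Da
.ELEMENT_MASS <- c(
  C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, F = 18.99840322, Cl = 34.96885268,
  Br = 78.9183371, I = 126.904473
)

.PROTON_MASS <- 1.007276466879

#' Element alphabet used for molecular formulas
#'
#' @return character vector of supported element symbols in canonical order
#'   (C, H, then alphabetical).
#' @export
formulaElements <- function() .ELEMENTS

#' Construct an empty molecular formula
#'
#' @return named integer vector with a zero count for every supported
#'   element.
#' @export
emptyFormula <- function() {
  setNames(integer(length(.ELEMENTS)), .ELEMENTS)
}

#' Parse a molecular formula string
#'
#' Accepts plain Hill-style strings such as `"C6H12O6"` or `"C2H3ClO"`.
#' Element symbols outside the supported alphabet are an error.
#'
#' @param x formula string.
#' @return named integer vector of element counts.
#' @examples
#' parseFormula("C6H12O6")
#' @export
parseFormula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  f <- emptyFormula()
  if (x == "" || x == "0") return(f)
  m <- gregexpr("([A-Z][a-z]?)(-?[0-9]*)", x, perl = TRUE)[[1]]
  tokens <- regmatches(x, gregexpr("([A-Z][a-z]?)(-?[0-9]*)", x, perl = TRUE))[[1]]
  if (paste(tokens, collapse = "") != x)
    stop("cannot parse formula string: '", x, "'", call. = FALSE)
  for (tok in tokens) {
    sym <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
    num <- sub("^[A-Z][a-z]?", "", tok)
    if (!(sym %in% .ELEMENTS))
      stop("unsupported element '", sym, "' in formula '", x, "'",
           call. = FALSE)
    n <- if (num == "") 1L else as.integer(num)
    f[sym] <- f[sym] + n
  }
  f
}

#' Canonical string form of a molecular formula
#'
#' Hill order: carbon, hydrogen, then the remaining elements alphabetically.
#' Negative counts (invalid formulas) are rendered with explicit negative
#' subscripts so the invalidity is visible.
#'
#' @param f named integer vector of element counts.
#' @return single string; `"0"` for the empty formula.
#' @export
formulaToString <- function(f) {
  f <- asFormula(f)
  ord <- c("C", "H", sort(setdiff(.ELEMENTS, c("C", "H"))))
  parts <- character(0)
  for (el in ord) {
    n <- f[[el]]
    if (n == 0L) next
    parts <- c(parts, if (n == 1L) el else paste0(el, n))
  }
  if (!length(parts)) "0" else paste(parts, collapse = "")
}

## coerce a user-supplied formula (string or named vector) to the internal
## fixed-order integer vector
asFormula <- function(f) {
  if (is.character(f)) return(parseFormula(f))
  stopifnot(is.numeric(f))
  if (is.null(names(f))) {
    if (length(f) != length(.ELEMENTS))
      stop("unnamed formula vector must have length ", length(.ELEMENTS))
    return(setNames(as.integer(f), .ELEMENTS))
  }
  bad <- setdiff(names(f), .ELEMENTS)
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  out <- emptyFormula()
  out[names(f)] <- as.integer(f)
  out
}

#' Element-wise formula arithmetic
#'
#' `formulaSubtract()` removes a neutral loss from a formula; the result may
#' have negative counts, in which case it is chemically impossible and
#' `isValidFormula()` returns `FALSE`. Invalidity is a value, not an error.
#'
#' @param a,b formulas (strings or named integer count vectors).
#' @return named integer vector of element counts.
#' @examples
#' formulaSubtract("C6H12O6", "H2O")        # C6H10O5, valid
#' isValidFormula(formulaSubtract("C2H4", "H2O"))  # FALSE: no oxygen to lose
#' @export
formulaSubtract <- function(a, b) asFormula(a) - asFormula(b)

#' @rdname formulaSubtract
#' @export
formulaAdd <- function(a, b) asFormula(a) + asFormula(b)

#' @rdname formulaSubtract
#' @export
isValidFormula <- function(f) all(asFormula(f) >= 0L)

#' Monoisotopic mass of a molecular formula
#'
#' @param f formula (string or named integer count vector).
#' @return neutral monoisotopic mass in Da.
#' @export
formulaMass <- function(f) {
  f <- asFormula(f)
  sum(f * .ELEMENT_MASS[.ELEMENTS])
}

#' Ion m/z of a formula assuming protonation
#'
#' All libraries handled here are restricted to positive ion mode, so node
#' and fragment masses are computed as the neutral monoisotopic mass plus
#' one proton, i.e. the \[M+H\]+ ion.
#'
#' @param f formula (string or named integer count vector).
#' @return m/z of the singly protonated ion in Da.
#' @export
ionMass <- function(f) formulaMass(f) + .PROTON_MASS

#' @rdname ionMass
#' @export
protonMass <- function() .PROTON_MASS
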