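# Molecular-formula algebra over the CHNOPS element set.
#
# Formulas are represented as integer count matrices with one row per
# formula and columns C, H, N, O, P, S (Hill order for carbon-containing
# formulas; for the supported elements the same column order is also
# alphabetical once C and H are placed first, so a single storage order
# serves both Hill cases). Signed matrices represent formula differences.

.empty_counts <- function(n) {
  matrix(0L, nrow = n, ncol = length(ELEMENTS),
         dimnames = list(NULL, ELEMENTS))
}

.as_counts <- function(f) {
  if (is.character(f)) return(parse_formula(f))
  if (is.matrix(f)) {
    if (!all(ELEMENTS %in% colnames(f)))
      stop("formula matrix must have columns ", paste(ELEMENTS, collapse = ","))
    m <- f[, ELEMENTS, drop = FALSE]
    storage.mode(m) <- "integer"
    return(m)
  }
  if (is.numeric(f) && !is.null(names(f))) {
    m <- .empty_counts(1L)
    bad <- setdiff(names(f), ELEMENTS)
    if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ","))
    m[1L, names(f)] <- as.integer(f)
    return(m)
  }
  stop("cannot interpret object as molecular formula(s)")
}

#' Parse molecular formulas
#'
#' Parses formula strings such as `"C6H12O6"` into an integer count matrix
#' over the elements C, H, N, O, P and S. Multi-digit counts and implicit
#' counts of 1 are supported.
#'
#' @param x Character vector of formula strings.
#' @return Integer matrix with one row per input string and columns
#'   `C,H,N,O,P,S`.
#' @seealso [format_formula()] for the inverse operation.
#' @export
#' @examples
#' parse_formula(c("C6H12O6", "H2O"))
parse_formula <- function(x) {
  if (!is.character(x) || length(x) < 1L)
    stop("'x' must be a non-empty character vector")
  out <- .empty_counts(length(x))
  for (i in seq_along(x)) {
    s <- x[[i]]
    if (is.na(s) || !nzchar(s)) stop("empty formula string at position ", i)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1L]]
    toks <- regmatches(s, list(m))[[1L]]
    if (sum(attr(m, "match.length")) != nchar(s) || !length(toks))
      stop("malformed formula string: '", s, "'")
    for (tok in toks) {
      el <- sub("[0-9]*$", "", tok)
      if (!el %in% ELEMENTS)
        stop("unknown element symbol '", el, "' in '", s,
             "' (supported: ", paste(ELEMENTS, collapse = ","), ")")
      num <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(num)) as.integer(num) else 1L
      out[i, el] <- out[i, el] + n
    }
  }
  out
}

#' Format molecular formulas in Hill notation
#'
#' Inverse of [parse_formula()]: carbon first, hydrogen second, remaining
#' elements alphabetically; elements with zero count are omitted and counts
#' of 1 are implicit.
#'
#' @param f Formula count matrix (or character vector, which is passed
#'   through a parse/format round trip).
#' @return Character vector of canonical formula strings.
#' @export
#' @examples
#' format_formula(parse_formula("H2O"))
format_formula <- function(f) {
  fm <- .as_counts(f)
  apply(fm, 1L, function(cnt) {
    keep <- cnt > 0L
    if (!any(keep)) return("")
    paste0(ELEMENTS[keep], ifelse(cnt[keep] > 1L, cnt[keep], ""),
           collapse = "")
  })
}

# Canonical hash key for a formula (or signed difference) count row.
.formula_key <- function(fm) {
  do.call(paste, c(split(fm, col(fm)), sep = " "))
}

#' Monoisotopic mass
#'
#' Sum over elements of count times the exact mass of the lightest isotope,
#' using the package's pinned isotope table.
#'
#' @param f Formula(s): character vector or count matrix.
#' @return Numeric vector of neutral monoisotopic masses (Da).
#' @export
#' @examples
#' monoisotopic_mass("C6H12O6")
monoisotopic_mass <- function(f) {
  fm <- .as_counts(f)
  if (any(fm < 0L))
    stop("monoisotopic_mass() is defined for non-negative formulas only")
  as.numeric(fm %*% ELEMENT_MASS)
}

#' Formula difference
#'
#' Component-wise difference `a - b`; the result is a signed count matrix
#' and may contain negative entries.
#'
#' @param a,b Formulas (character or count matrix). One of the two may have
#'   a single row, in which case it is recycled against the other.
#' @return Signed integer count matrix.
#' @export
#' @examples
#' formula_difference("C6H13O9P", "C6H12O6")
formula_difference <- function(a, b) {
  am <- .as_counts(a); bm <- .as_counts(b)
  if (nrow(am) == 1L && nrow(bm) > 1L) am <- am[rep(1L, nrow(bm)), , drop = FALSE]
  if (nrow(bm) == 1L && nrow(am) > 1L) bm <- bm[rep(1L, nrow(am)), , drop = FALSE]
  if (nrow(am) != nrow(bm)) stop("incompatible numbers of formulas")
  am - bm
}

#' Ion m/z for a singly charged positive adduct
#'
#' `ion m/z = neutral monoisotopic mass + adduct atom mass - electron mass`.
#' The electron mass is subtracted because the ion has lost one electron;
#' omitting it shifts masses by about 2.7 ppm at m/z 200, well outside a
#' 2 ppm tolerance.
#'
#' @param f Formula(s): character vector or count matrix.
#' @param adduct Adduct label(s), one of `names(adducts())`; recycled
#'   against the formulas.
#' @return Numeric vector of ion m/z values (Th).
#' @export
#' @examples
#' ion_mz("C6H12O6", "[M+Na]+")
ion_mz <- function(f, adduct = "[M+H]+") {
  bad <- setdiff(unique(adduct), names(ADDUCT_MASS))
  if (length(bad))
    stop("unknown adduct(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(names(ADDUCT_MASS), collapse = ", "), ")")
  monoisotopic_mass(f) + unname(ADDUCT_MASS[adduct]) - ELECTRON_MASS
}

#' Neutral mass window targeted by an ion m/z
#'
#' Inverts [ion_mz()] for a measured m/z and ppm tolerance.
#'
#' @param mz Measured ion m/z (Th).
#' @param adduct Adduct label.
#' @param tol_ppm Mass tolerance in ppm (relative to the measured m/z).
#' @return Numeric vector `c(lo, hi)` of neutral masses (Da).
#' @export
neutral_mass_window <- function(mz, adduct = "[M+H]+", tol_ppm = 2) {
  if (!adduct %in% names(ADDUCT_MASS)) stop("unknown adduct: ", adduct)
  lohi <- mz * (1 + c(-1, 1) * tol_ppm * 1e-6)
  lohi - ADDUCT_MASS[[adduct]] + ELECTRON_MASS
}
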