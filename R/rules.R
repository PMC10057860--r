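#' Elemental plausibility rules for candidate formulas
#'
#' Container for the constraints a candidate molecular formula must satisfy:
#' allowed elements, hydrogen/carbon ratio bounds, neutral mass bounds and
#' optional per-element count bounds. Defaults follow common practice for
#' serum metabolites measured in positive-mode DI-HRMS: CHNOPS elements,
#' H/C in \[0.4, 5.1\] and neutral mass in \[50, 800\] Da. An optional
#' ring-and-double-bond-equivalent (RDBE) range can be enabled; it is off by
#' default.
#'
#' @param elements Character vector of allowed element symbols (subset of
#'   C,H,N,O,P,S).
#' @param hc_ratio Numeric length-2, lower/upper bound on the H/C ratio;
#'   applied only to formulas with at least one carbon (the ratio is
#'   undefined at C = 0, so carbon-free formulas skip this test).
#' @param mass_range Numeric length-2, neutral monoisotopic mass bounds (Da).
#' @param min_counts,max_counts Optional named integer vectors of per-element
#'   minimum / maximum counts.
#' @param rdbe Optional numeric length-2 RDBE bounds, computed as
#'   `C - H/2 + N/2 + P/2 + 1`; `NULL` (default) disables the test.
#' @return An object of class `element_rules`.
#' @export
#' @examples
#' r <- element_rules()
#' check_constraints("C6H12O6", r)
element_rules <- function(elements = ELEMENTS,
                          hc_ratio = c(0.4, 5.1),
                          mass_range = c(50, 800),
                          min_counts = NULL,
                          max_counts = NULL,
                          rdbe = NULL) {
  elements <- match.arg(elements, ELEMENTS, several.ok = TRUE)
  if (length(elements) < 1L) stop("allowed element set must be non-empty")
  stopifnot(length(hc_ratio) == 2L, hc_ratio[1] <= hc_ratio[2],
            length(mass_range) == 2L, all(mass_range > 0),
            mass_range[1] <= mass_range[2])
  mins <- stats::setNames(rep(0L, length(ELEMENTS)), ELEMENTS)
  maxs <- stats::setNames(rep(NA_integer_, length(ELEMENTS)), ELEMENTS)
  if (!is.null(min_counts)) mins[names(min_counts)] <- as.integer(min_counts)
  if (!is.null(max_counts)) maxs[names(max_counts)] <- as.integer(max_counts)
  if (!is.null(rdbe)) stopifnot(length(rdbe) == 2L, rdbe[1] <= rdbe[2])
  structure(list(elements = elements, hc_ratio = as.numeric(hc_ratio),
                 mass_range = as.numeric(mass_range),
                 min_counts = mins, max_counts = maxs, rdbe = rdbe),
            class = "element_rules")
}

#' @export
print.element_rules <- function(x, ...) {
  cat("Element rules\n")
  cat("  elements:  ", paste(x$elements, collapse = ","), "\n")
  cat("  H/C ratio: ", x$hc_ratio[1], "-", x$hc_ratio[2],
      " (skipped when C = 0)\n", sep = "")
  cat("  mass range:", x$mass_range[1], "-", x$mass_range[2], "Da\n")
  if (!is.null(x$rdbe)) cat("  RDBE:      ", x$rdbe[1], "-", x$rdbe[2], "\n")
  invisible(x)
}

#' Ring and double bond equivalents
#'
#' `RDBE = C - H/2 + N/2 + P/2 + 1` (trivalent N and P convention).
#'
#' @param f Formula(s): character vector or count matrix.
#' @return Numeric vector.
#' @export
rdbe <- function(f) {
  fm <- .as_counts(f)
  unname(fm[, "C"] - fm[, "H"] / 2 + fm[, "N"] / 2 + fm[, "P"] / 2 + 1)
}

#' Check formulas against elemental rules
#'
#' Tests, in order: allowed elements, per-element count bounds, the H/C
#' ratio (only when C > 0), the neutral mass range, and (if enabled) RDBE.
#' The first failing test gives the reported reason.
#'
#' @param f Formula(s): character vector or count matrix.
#' @param rules An [element_rules()] object.
#' @return Logical vector, one entry per formula, with attribute `"reason"`
#'   (character; `""` for passing formulas, otherwise one of `"elements"`,
#'   `"count_bounds"`, `"hc_ratio"`, `"mass_range"`, `"rdbe"`, `"empty"`).
#' @export
#' @examples
#' check_constraints(c("C6H12O6", "C10H2", "CH6"), element_rules())
check_constraints <- function(f, rules = element_rules()) {
  fm <- .as_counts(f)
  n <- nrow(fm)
  reason <- character(n)
  ok <- rep(TRUE, n)
  fail <- function(idx, why) {
    idx <- idx & ok
    reason[idx] <<- why
    ok[idx] <<- FALSE
  }
  fail(rowSums(fm) <= 0L | apply(fm < 0L, 1L, any), "empty")
  banned <- setdiff(ELEMENTS, rules$elements)
  if (length(banned))
    fail(rowSums(fm[, banned, drop = FALSE] > 0L) > 0L, "elements")
  lo <- rules$min_counts; hi <- rules$max_counts
  below <- sweep(fm, 2L, lo, "<")
  over <- !is.na(rep(hi, each = n)) & sweep(fm, 2L, ifelse(is.na(hi), .Machine$integer.max, hi), ">")
  fail(apply(below | over, 1L, any), "count_bounds")
  hasC <- fm[, "C"] > 0L
  ratio <- ifelse(hasC, fm[, "H"] / pmax(fm[, "C"], 1L), NA_real_)
  fail(hasC & (ratio < rules$hc_ratio[1] | ratio > rules$hc_ratio[2]), "hc_ratio")
  mass <- as.numeric(pmax(fm, 0L) %*% ELEMENT_MASS)
  fail(mass < rules$mass_range[1] | mass > rules$mass_range[2], "mass_range")
  if (!is.null(rules$rdbe)) {
    d <- rdbe(fm)
    fail(d < rules$rdbe[1] | d > rules$rdbe[2], "rdbe")
  }
  attr(ok, "reason") <- reason
  ok
}
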