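# Candidate-formula generation: exhaustive enumeration of CHNOPS formulas
# whose ion m/z falls within a ppm tolerance of a measured feature.

.max_counts_for <- function(rules, hi) {
  maxc <- pmin(floor(hi / ELEMENT_MASS),
               ifelse(is.na(rules$max_counts), .Machine$integer.max,
                      rules$max_counts))
  maxc[!ELEMENTS %in% rules$elements] <- 0L
  as.integer(pmax(maxc, 0L))
}

#' Generate candidate formulas for a measured m/z
#'
#' For each adduct, inverts the ion relationship to a neutral target mass
#' window and enumerates every CHNOPS formula in that window (exhaustively,
#' with per-element bounds derived from the window mass), then applies the
#' elemental rules. The neutral mass bounds of `rules` are intersected with
#' the ppm window, so candidates always lie in the configured mass domain.
#'
#' @param mz Measured ion m/z (Th).
#' @param adducts Character vector of adduct labels (default the three
#'   positive-mode adducts `[M+H]+`, `[M+Na]+`, `[M+K]+`).
#' @param tol_ppm Mass tolerance in ppm (default 2).
#' @param rules An [element_rules()] object.
#' @return A data.frame of class `candidate_set` with columns `adduct`,
#'   `formula`, the element counts `C,H,N,O,P,S`, `mz_theo` and `ppm_error`
#'   (signed, theoretical minus experimental relative to experimental).
#'   Rows are ordered by theoretical m/z then adduct, independent of the
#'   order of `adducts`; `(adduct, formula)` pairs are unique. The measured
#'   m/z is attached as attribute `"mz"`.
#' @export
#' @examples
#' generate_candidates(ion_mz("C6H12O6", "[M+H]+"))
generate_candidates <- function(mz, adducts = names(ADDUCT_MASS),
                                tol_ppm = 2, rules = element_rules()) {
  stopifnot(length(mz) == 1L, mz > 0, tol_ppm > 0)
  adducts <- unique(adducts)
  bad <- setdiff(adducts, names(ADDUCT_MASS))
  if (length(bad)) stop("unknown adduct(s): ", paste(bad, collapse = ", "))
  pieces <- lapply(adducts, function(ad) {
    w <- neutral_mass_window(mz, ad, tol_ppm)
    lo <- max(w[1], rules$mass_range[1])
    hi <- min(w[2], rules$mass_range[2])
    if (lo > hi) return(NULL)
    fm <- enumerate_formulas_cpp(lo, hi, unname(ELEMENT_MASS),
                                 .max_counts_for(rules, hi))
    if (nrow(fm) == 0L) return(NULL)
    fm <- fm[check_constraints(fm, rules), , drop = FALSE]
    if (nrow(fm) == 0L) return(NULL)
    mz_theo <- ion_mz(fm, ad)
    ppm <- (mz_theo - mz) / mz * 1e6
    keep <- abs(ppm) <= tol_ppm
    if (!any(keep)) return(NULL)
    fm <- fm[keep, , drop = FALSE]
    data.frame(adduct = ad, formula = format_formula(fm), fm,
               mz_theo = mz_theo[keep], ppm_error = ppm[keep])
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(adduct = character(), formula = character(),
                      .empty_counts(0L), mz_theo = numeric(),
                      ppm_error = numeric())
  out <- out[!duplicated(paste(out$adduct, out$formula)), , drop = FALSE]
  out <- out[order(out$mz_theo, out$adduct), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mz") <- mz
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Candidate counts for a list of m/z values
#'
#' Convenience profile of how many formula candidates each feature obtains;
#' monotone non-decreasing in `tol_ppm`.
#'
#' @param mz_list Numeric vector of ion m/z values.
#' @inheritParams generate_candidates
#' @return Integer vector of candidate counts, one per input m/z.
#' @export
candidate_count_profile <- function(mz_list, adducts = names(ADDUCT_MASS),
                                    tol_ppm = 2, rules = element_rules()) {
  vapply(mz_list, function(m)
    nrow(generate_candidates(m, adducts, tol_ppm, rules)), integer(1))
}
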