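# Candidate scoring: a weighted combination of network degree, mass
# accuracy and isotopic-pattern similarity,
#
#   total = w_degree * S_degree - w_mz * S_mz + w_iso * S_iso
#
# where S_mz is a pure penalty (ppm error normalized by the tolerance) and
# S_degree, S_iso lie in [0, 1].

#' Score weights
#'
#' Weight coefficients of the three scoring criteria. The defaults
#' (degree 0.5, mass accuracy 0.3, isotope similarity 0.2) are the
#' combination found to give the best correct-assignment rate on reference
#' standards; all-degree or all-mass weightings are recovered as limiting
#' cases.
#'
#' @param degree,mz,iso Non-negative weights.
#' @return Object of class `score_weights`.
#' @export
score_weights <- function(degree = 0.5, mz = 0.3, iso = 0.2) {
  stopifnot(degree >= 0, mz >= 0, iso >= 0)
  structure(list(degree = degree, mz = mz, iso = iso),
            class = "score_weights")
}

#' Mass-accuracy score (penalty term)
#'
#' Absolute ppm error normalized by the mass tolerance:
#' `|mz_exp - mz_theo| / mz_exp * 1e6 / tol_ppm`. Zero for an exact match,
#' 1 at the tolerance boundary, and symmetric in the sign of the error. It
#' enters the total score with a minus sign, so a larger error always
#' lowers the total.
#'
#' @param mz_exp,mz_theo Experimental and theoretical m/z (Th); vectorized.
#' @param tol_ppm Mass tolerance in ppm (default 2).
#' @param normalized If `FALSE`, return the raw absolute ppm error instead
#'   of normalizing by the tolerance (an alternative penalty scale; the
#'   ranking within a fixed tolerance is unchanged, only the weight of the
#'   mass term relative to the other scores).
#' @return Non-negative numeric vector.
#' @export
score_mz <- function(mz_exp, mz_theo, tol_ppm = 2, normalized = TRUE) {
  ppm <- abs(mz_exp - mz_theo) / mz_exp * 1e6
  if (normalized) ppm / tol_ppm else ppm
}

# Closed-form M+1 shell of one or more formulas (rows of a count matrix):
# relative intensity r = sum_e n_e * a_e(+1)/a_e(mono), exact for the
# aggregated shell; mean mass offset is the abundance-weighted isotope
# mass shift. Cross-checked against isotope_pattern() in the tests.
.M1_RATE <- local({
  r <- off <- numeric(length(ELEMENTS)); names(r) <- names(off) <- ELEMENTS
  for (e in ELEMENTS) {
    iso <- .ISOTOPES[[e]]
    shift <- round(iso$mass - iso$mass[1L])
    one <- which(shift == 1)
    if (length(one)) {
      r[e] <- sum(iso$abundance[one]) / iso$abundance[1L]
      off[e] <- sum(iso$abundance[one] * (iso$mass[one] - iso$mass[1L])) /
        sum(iso$abundance[one])
    }
  }
  list(rate = r, offset = off)
})

.m1_shell <- function(fm) {
  contrib <- sweep(fm, 2L, .M1_RATE$rate, "*")
  rel <- rowSums(contrib)
  off <- rowSums(sweep(contrib, 2L, .M1_RATE$offset, "*")) / ifelse(rel > 0, rel, NA_real_)
  list(rel_intensity = rel, offset = off)
}

#' Isotopic-pattern similarity score
#'
#' Compares the experimental and theoretical M+1 shell:
#' `S_iso = 0.5 * S_mz + 0.5 * S_int`, where
#' `S_mz = 1 - (ppm error of the M+1 m/z) / tol_ppm` and
#' `S_int = 1 - (|int_exp - int_theo| / int_theo) / tol_int`, each floored
#' at 0. With the default relative-intensity tolerance of 5 (i.e. 500%),
#' an exact m/z with a 500% intensity deviation scores 0.5. If no
#' experimental M+1 peak was detected the score is 0: absence of isotope
#' evidence neither supports nor (strongly) contradicts a candidate.
#'
#' @param pattern_exp Experimental pattern: a data.frame with columns `mz`
#'   and `rel_intensity` containing at least the monoisotopic row and (if
#'   detected) the M+1 row, or `NULL`/single-row if no M+1 was detected.
#' @param pattern_theo Theoretical pattern as returned by
#'   [isotope_pattern()] (neutral masses are fine: only the M+1 offset and
#'   relative intensity are used, which are unaffected by the adduct).
#' @param tol_ppm Mass tolerance in ppm (default 2).
#' @param tol_int Relative-intensity tolerance as a fraction (default 5,
#'   i.e. 500%).
#' @return A score in \[0, 1\].
#' @export
score_iso <- function(pattern_exp, pattern_theo, tol_ppm = 2, tol_int = 5) {
  if (is.null(pattern_exp) || nrow(pattern_exp) < 2L) return(0)
  theo1 <- pattern_theo[pattern_theo$shell == 1L, , drop = FALSE]
  theo0 <- pattern_theo[pattern_theo$shell == 0L, , drop = FALSE]
  if (nrow(theo1) == 0L) return(0)
  exp0 <- pattern_exp[1L, ]; exp1 <- pattern_exp[2L, ]
  d_exp <- exp1$mz - exp0$mz
  d_theo <- theo1$mz - theo0$mz
  .score_iso_m1(d_exp, exp1$rel_intensity / exp0$rel_intensity,
                d_theo, theo1$rel_intensity,
                mz_ref = exp1$mz, tol_ppm = tol_ppm, tol_int = tol_int)
}

# Vectorized M+1 comparison on mass offsets and relative intensities.
.score_iso_m1 <- function(off_exp, int_exp, off_theo, int_theo, mz_ref,
                          tol_ppm = 2, tol_int = 5) {
  ppm <- abs(off_exp - off_theo) / mz_ref * 1e6
  s_mz <- pmax(0, 1 - ppm / tol_ppm)
  s_int <- pmax(0, 1 - (abs(int_exp - int_theo) / int_theo) / tol_int)
  out <- 0.5 * s_mz + 0.5 * s_int
  out[is.na(out)] <- 0
  out
}

#' Degree score
#'
#' Per-feature max-normalized network degree: each candidate's degree
#' divided by the maximum degree among that feature's candidates, giving a
#' score in (0, 1] commensurate with the other terms; a lone candidate
#' scores 1.
#'
#' @param degrees Integer vector of candidate degrees for one feature.
#' @return Numeric vector of scores.
#' @export
score_degree <- function(degrees) {
  if (length(degrees) == 0L) return(numeric(0))
  m <- max(degrees)
  if (m <= 0) return(rep(0, length(degrees)))
  degrees / m
}

#' Total candidate score
#'
#' `w_degree * S_degree - w_mz * S_mz + w_iso * S_iso`. The mass term is a
#' penalty and keeps its minus sign; the degree and isotope components are
#' floored at 0 before weighting so the total is bounded.
#'
#' @param s_degree,s_mz,s_iso Component scores (vectorized).
#' @param weights A [score_weights()] object.
#' @return Numeric vector of total scores.
#' @export
#' @examples
#' total_score(1, 0, 1, score_weights()) # 0.7 with the default weights
total_score <- function(s_degree, s_mz, s_iso, weights = score_weights()) {
  weights$degree * pmax(0, s_degree) - weights$mz * s_mz +
    weights$iso * pmax(0, s_iso)
}
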