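# Shell-aggregated isotopic patterns.
#
# The pattern is aggregated by nominal mass shift ("shells" M+0, M+1, M+2,
# ...), not resolved into isotopic fine structure: the isotope-similarity
# score compares a single experimental/theoretical (m/z, intensity) pair per
# shell, which aggregation provides directly. Shell intensities are exact
# polynomial expansions of the natural abundances; the shell m/z is the
# abundance-weighted mean isotopologue mass within the shell.

# Convolution of two (probability, probability-weighted mass-offset)
# polynomials truncated at kmax shells.
.shell_conv <- function(a, b, kmax) {
  n <- kmax + 1L
  p <- numeric(n); pm <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n - i + 1L)) {
      k <- i + j - 1L
      p[k] <- p[k] + a$p[i] * b$p[j]
      pm[k] <- pm[k] + a$p[i] * b$pm[j] + b$p[j] * a$pm[i]
    }
  }
  list(p = p, pm = pm)
}

.atom_poly <- function(element, kmax) {
  iso <- .ISOTOPES[[element]]
  shift <- as.integer(round(iso$mass - iso$mass[1L]))
  p <- numeric(kmax + 1L); pm <- numeric(kmax + 1L)
  for (i in seq_along(shift)) {
    if (shift[i] <= kmax) {
      p[shift[i] + 1L] <- p[shift[i] + 1L] + iso$abundance[i]
      pm[shift[i] + 1L] <- pm[shift[i] + 1L] +
        iso$abundance[i] * (iso$mass[i] - iso$mass[1L])
    }
  }
  list(p = p, pm = pm)
}

#' Theoretical isotopic pattern (shell-aggregated)
#'
#' Computes relative intensities and mean m/z of the M+1, M+2, ...
#' isotopologue shells of a neutral formula from natural isotope
#' abundances (13C, 2H, 15N, 17/18O, 33/34/36S). Intensities are relative
#' to the monoisotopic peak, whose entry is always exactly 1.
#'
#' @param f A single formula (string or one-row count matrix).
#' @param max_shells Number of shells beyond monoisotopic (default 2:
#'   M+1 and M+2).
#' @return A data.frame with columns `shell` (0 = monoisotopic), `mz`
#'   (neutral shell mass, Da) and `rel_intensity` (fraction of the
#'   monoisotopic intensity), ordered by m/z.
#' @export
#' @examples
#' isotope_pattern("C6H12O6")
isotope_pattern <- function(f, max_shells = 2L) {
  fm <- .as_counts(f)
  if (nrow(fm) != 1L) stop("isotope_pattern() expects a single formula")
  if (any(fm < 0L)) stop("isotope_pattern() requires a non-difference formula")
  max_shells <- as.integer(max_shells)
  if (max_shells < 1L) stop("max_shells must be >= 1")
  poly <- list(p = c(1, numeric(max_shells)), pm = numeric(max_shells + 1L))
  for (e in ELEMENTS) {
    n_atoms <- fm[1L, e]
    if (n_atoms == 0L) next
    ap <- .atom_poly(e, max_shells)
    for (i in seq_len(n_atoms)) poly <- .shell_conv(poly, ap, max_shells)
  }
  mono <- monoisotopic_mass(fm)
  rel <- poly$p / poly$p[1L]
  off <- ifelse(poly$p > 0, poly$pm / poly$p, NA_real_)
  out <- data.frame(shell = 0:max_shells, mz = mono + off, rel_intensity = rel)
  out[out$rel_intensity > 0 & !is.na(out$mz), , drop = FALSE]
}
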