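# Independent oracles used to validate the fast implementations. They are
# deliberately written as naive loops / exhaustive enumerations so they
# share no code path with the package internals they check.

ORACLE_MASS <- c(C = 12.0, H = 1.0078250319, N = 14.0030740044,
                 O = 15.9949146196, P = 30.9737619984, S = 31.9720711744)

# Naive nested-loop enumeration of CHNOPS formulas with neutral
# monoisotopic mass in [lo, hi]. Loops run over P, S, N, O explicitly;
# for each combination the feasible C range is scanned and H solved.
oracle_enumerate <- function(lo, hi) {
  out <- list()
  for (p in 0:floor(hi / ORACLE_MASS["P"])) {
    for (s in 0:floor((hi - p * ORACLE_MASS["P"]) / ORACLE_MASS["S"])) {
      m_ps <- p * ORACLE_MASS["P"] + s * ORACLE_MASS["S"]
      for (n in 0:floor((hi - m_ps) / ORACLE_MASS["N"])) {
        m_psn <- m_ps + n * ORACLE_MASS["N"]
        for (o in 0:floor((hi - m_psn) / ORACLE_MASS["O"])) {
          m_psno <- m_psn + o * ORACLE_MASS["O"]
          for (cc in 0:floor((hi - m_psno) / ORACLE_MASS["C"])) {
            base <- m_psno + cc * ORACLE_MASS["C"]
            h_lo <- ceiling((lo - base) / ORACLE_MASS["H"] - 1e-9)
            h_hi <- floor((hi - base) / ORACLE_MASS["H"] + 1e-9)
            if (h_hi < 0) next
            for (h in max(h_lo, 0):h_hi) {
              if (cc + h + n + o + p + s == 0) next
              m <- base + h * ORACLE_MASS["H"]
              if (m >= lo && m <= hi)
                out[[length(out) + 1L]] <-
                  c(C = cc, H = h, N = n, O = o, P = p, S = s)
            }
          }
        }
      }
    }
  }
  if (!length(out)) return(matrix(0L, 0, 6, dimnames = list(NULL, names(ORACLE_MASS))))
  do.call(rbind, out)
}

# Oracle candidate formulas for a measured ion m/z: enumerate, then apply
# the H/C ratio and mass-range rules by direct arithmetic.
oracle_candidates <- function(mz, adduct, tol_ppm = 2,
                              hc = c(0.4, 5.1), mass_range = c(50, 800)) {
  add_mass <- c("[M+H]+" = 1.0078250319, "[M+Na]+" = 22.9897692820,
                "[M+K]+" = 38.9637064864)[[adduct]]
  e_mass <- 0.000548579909
  lo <- mz * (1 - tol_ppm * 1e-6) - add_mass + e_mass
  hi <- mz * (1 + tol_ppm * 1e-6) - add_mass + e_mass
  fm <- oracle_enumerate(max(lo, mass_range[1]), min(hi, mass_range[2]))
  keep <- logical(nrow(fm))
  for (i in seq_len(nrow(fm))) {
    ok <- TRUE
    if (fm[i, "C"] > 0) {
      r <- fm[i, "H"] / fm[i, "C"]
      ok <- r >= hc[1] && r <= hc[2]
    }
    m <- sum(fm[i, ] * ORACLE_MASS)
    ok <- ok && m >= mass_range[1] && m <= mass_range[2]
    ion <- m + add_mass - e_mass
    ok <- ok && abs(ion - mz) / mz * 1e6 <= tol_ppm
    keep[i] <- ok
  }
  fm <- fm[keep, , drop = FALSE]
  sort(apply(fm, 1L, function(x) paste(x, collapse = " ")))
}

# Brute-force isotopologue enumeration: every way of distributing each
# element's atoms over its isotopes, with multinomial probabilities.
# Returns shell relative intensities (vs monoisotopic) and mean shell
# mass offsets.
oracle_isotope <- function(counts, max_shell = 2) {
  iso <- list(
    C = cbind(mass = c(12.0, 13.0033548351), ab = c(0.9893, 0.0107)),
    H = cbind(mass = c(1.0078250319, 2.0141017781), ab = c(0.999885, 0.000115)),
    N = cbind(mass = c(14.0030740044, 15.0001088989), ab = c(0.99636, 0.00364)),
    O = cbind(mass = c(15.9949146196, 16.9991317565, 17.9991596129),
              ab = c(0.99757, 0.00038, 0.00205)),
    P = cbind(mass = 30.9737619984, ab = 1),
    S = cbind(mass = c(31.9720711744, 32.9714589098, 33.9678670040,
                       35.9670807100),
              ab = c(0.9499, 0.0075, 0.0425, 0.0001)))
  # compositions of n atoms over k isotopes
  compositions <- function(n, k) {
    if (k == 1L) return(matrix(n, 1, 1))
    out <- NULL
    for (i in 0:n) {
      sub <- compositions(n - i, k - 1L)
      out <- rbind(out, cbind(i, sub))
    }
    out
  }
  all_states <- data.frame(p = 1, mass = 0, shift = 0)
  for (e in names(iso)) {
    n <- counts[[e]]
    if (is.null(n) || is.na(n) || n == 0) next
    tab <- iso[[e]]
    k <- nrow(tab)
    comps <- compositions(n, k)
    elem_states <- do.call(rbind, lapply(seq_len(nrow(comps)), function(r) {
      cnt <- comps[r, ]
      p <- exp(lfactorial(n) - sum(lfactorial(cnt)) +
                 sum(cnt * log(tab[, "ab"])))
      data.frame(p = p, mass = sum(cnt * tab[, "mass"]),
                 shift = sum(cnt * round(tab[, "mass"] - tab[1, "mass"])))
    }))
    # full cross product of accumulated states with this element's states
    idx <- expand.grid(a = seq_len(nrow(all_states)),
                       b = seq_len(nrow(elem_states)))
    all_states <- data.frame(
      p = all_states$p[idx$a] * elem_states$p[idx$b],
      mass = all_states$mass[idx$a] + elem_states$mass[idx$b],
      shift = all_states$shift[idx$a] + elem_states$shift[idx$b])
    all_states <- all_states[all_states$shift <= max_shell + 2, , drop = FALSE]
  }
  mono <- all_states[all_states$shift == 0, ]
  stopifnot(nrow(mono) == 1L)
  shells <- lapply(0:max_shell, function(sh) {
    sub <- all_states[all_states$shift == sh, ]
    if (nrow(sub) == 0L) return(NULL)
    data.frame(shell = sh,
               rel_intensity = sum(sub$p) / mono$p,
               mz = sum(sub$p * sub$mass) / sum(sub$p))
  })
  do.call(rbind, shells)
}

# O(n^2) all-pairs edge oracle: compare every unordered formula pair's
# componentwise difference (up to sign) against the reaction differences.
oracle_edges <- function(formulas, reaction_diffs) {
  fm <- formnet::parse_formula(formulas)
  rkeys <- apply(reaction_diffs, 1L, paste, collapse = " ")
  edges <- character(0)
  n <- nrow(fm)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- fm[j, ] - fm[i, ]
      if (paste(d, collapse = " ") %in% rkeys ||
          paste(-d, collapse = " ") %in% rkeys)
        edges <- c(edges, paste(i, j))
    }
  }
  sort(edges)
}

# small helper: canonical "i j" edge keys from a reaction_network
net_edge_keys <- function(net) {
  e <- net$edges
  sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
}
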