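# Formula algebra, masses, adduct ions, isotope patterns, element rules.

test_that("formula parsing reads counts exactly and rejects bad input", {
  fm <- parse_formula(c("C6H12O6", "H2O", "CH4", "C2H6NO2P"))
  expect_equal(unname(fm[1, ]), c(6L, 12L, 0L, 6L, 0L, 0L))
  expect_equal(unname(fm[2, c("H", "O")]), c(2L, 1L))
  expect_equal(unname(fm[4, ]), c(2L, 6L, 1L, 2L, 1L, 0L))
  expect_error(parse_formula("C6X2"), "unknown element")
  expect_error(parse_formula("Cl2"), "unknown element")
  expect_error(parse_formula(""), "empty")
  expect_error(parse_formula("c6h12"), "malformed")
})

test_that("parse/format round-trips on many random valid formulas", {
  set.seed(11)
  fm <- matrix(0L, 1000, 6, dimnames = list(NULL, c("C","H","N","O","P","S")))
  fm[, "C"] <- sample(0:40, 1000, TRUE)
  fm[, "H"] <- sample(1:80, 1000, TRUE)
  fm[, "N"] <- sample(0:8, 1000, TRUE)
  fm[, "O"] <- sample(0:15, 1000, TRUE)
  fm[, "P"] <- sample(0:3, 1000, TRUE)
  fm[, "S"] <- sample(0:3, 1000, TRUE)
  txt <- format_formula(fm)
  expect_equal(parse_formula(txt), fm, ignore_attr = TRUE)
  expect_equal(format_formula(parse_formula(txt)), txt)
})

test_that("monoisotopic masses match the pinned isotope table", {
  # frozen sums of tabulated lightest-isotope masses
  expect_equal(monoisotopic_mass("H2O"), 18.0105646834, tolerance = 1e-9)
  expect_equal(monoisotopic_mass("C6H12O6"), 180.0633881004, tolerance = 1e-9)
  expect_equal(monoisotopic_mass(c(C = 0)), 0)
  expect_error(monoisotopic_mass(formula_difference("C2H4", "C2H6")),
               "non-negative")
})

test_that("mass is additive over formula sums", {
  set.seed(5)
  for (i in 1:50) {
    a <- c(C = sample(0:20, 1), H = sample(1:40, 1), O = sample(0:10, 1),
           N = sample(0:5, 1))
    b <- c(C = sample(0:20, 1), H = sample(1:40, 1), S = sample(0:2, 1),
           P = sample(0:2, 1))
    ab <- formnet:::.as_counts(a) + formnet:::.as_counts(b)
    expect_equal(monoisotopic_mass(a) + monoisotopic_mass(b),
                 monoisotopic_mass(ab), tolerance = 1e-9)
  }
})

test_that("formula differences are componentwise and signed", {
  d <- formula_difference("C6H13O9P", "C6H12O6")
  expect_equal(unname(d[1, c("H", "O", "P")]), c(1L, 3L, 1L))
  expect_equal(unname(d[1, c("C", "N", "S")]), c(0L, 0L, 0L))
  expect_true(all(formula_difference("C5H9NO4", "C5H9NO4") == 0L))
  expect_equal(unname(formula_difference("C2H4", "C2H6")[1, "H"]), -2L)
})

test_that("ion m/z subtracts the electron and rejects unknown adducts", {
  # neutral mass + adduct atom mass - electron mass, from the pinned table
  expect_equal(ion_mz("C6H12O6", "[M+Na]+"), 203.0526088, tolerance = 1e-6)
  expect_equal(ion_mz("H2O", "[M+H]+"), 19.0178411, tolerance = 1e-6)
  expect_error(ion_mz("C6H12O6", "[M+Cs]+"), "unknown adduct")
  # protonation offset is one constant for every formula
  set.seed(7)
  f <- c("C3H7NO2", "C10H12N5O7P", "C20H30O2", "CH4", "C6H12O6")
  offs <- ion_mz(f, "[M+H]+") - monoisotopic_mass(f)
  expect_equal(max(offs) - min(offs), 0, tolerance = 1e-12)
  expect_equal(offs[1], 1.0078250319 - 0.000548579909, tolerance = 1e-9)
})

test_that("isotope patterns match brute-force isotopologue enumeration", {
  cases <- list(c(H = 2, O = 1), c(C = 1), c(C = 6, H = 12, O = 6),
                c(C = 5, H = 9, N = 1, O = 1, S = 1),
                c(C = 10, H = 16, N = 5, O = 13, P = 3))
  for (cnt in cases) {
    pat <- isotope_pattern(formnet:::.as_counts(cnt), max_shells = 2)
    ora <- oracle_isotope(as.list(cnt), max_shell = 2)
    for (sh in ora$shell) {
      p <- pat[pat$shell == sh, ]
      o <- ora[ora$shell == sh, ]
      expect_equal(p$rel_intensity, o$rel_intensity,
                   tolerance = 1e-6)
      expect_equal(p$mz, o$mz, tolerance = 1e-6)
    }
  }
  # monoisotopic entry is exactly 1 by construction
  expect_equal(isotope_pattern("C7H15NO3")$rel_intensity[1], 1)
  # single carbon: M+1 equals the 13C/12C abundance ratio
  expect_equal(isotope_pattern(c(C = 1), 1)$rel_intensity[2],
               0.0107 / 0.9893, tolerance = 1e-9)
  # water: M+1 from 2H and 17O only
  expect_equal(isotope_pattern(c(H = 2, O = 1), 1)$rel_intensity[2],
               2 * 0.000115 / 0.999885 + 0.00038 / 0.99757,
               tolerance = 1e-6)
})

test_that("closed-form M+1 shell agrees with the full pattern expansion", {
  set.seed(21)
  for (i in 1:20) {
    cnt <- c(C = sample(1:30, 1), H = sample(1:50, 1), N = sample(0:5, 1),
             O = sample(0:10, 1), P = sample(0:2, 1), S = sample(0:2, 1))
    fm <- formnet:::.as_counts(cnt)
    m1 <- formnet:::.m1_shell(fm)
    pat <- isotope_pattern(fm, max_shells = 1)
    expect_equal(m1$rel_intensity, pat$rel_intensity[2], tolerance = 1e-9)
    expect_equal(monoisotopic_mass(fm) + m1$offset, pat$mz[2],
                 tolerance = 1e-7)
  }
})

test_that("element rules test ratio, mass window and element set in order", {
  r <- element_rules()
  ok <- check_constraints(c("C6H12O6", "C10H2", "CH6"), r)
  expect_equal(unname(ok), c(TRUE, FALSE, FALSE), ignore_attr = TRUE)
  expect_equal(attr(ok, "reason")[2:3], c("hc_ratio", "hc_ratio"))
  # carbon-free formulas skip the H/C test
  expect_true(check_constraints("H3O4P", r))
  # mass window
  expect_equal(attr(check_constraints("CH4", r), "reason"), "mass_range")
  expect_equal(attr(check_constraints("C60H122", r), "reason"), "mass_range")
  # element restriction
  r2 <- element_rules(elements = c("C", "H", "O"))
  expect_equal(attr(check_constraints("C5H11NO2", r2), "reason"), "elements")
  # per-element bounds
  r3 <- element_rules(max_counts = c(S = 1))
  expect_equal(attr(check_constraints("C6H14O6S2", r3), "reason"),
               "count_bounds")
  # optional RDBE rule, off by default
  expect_true(check_constraints("C6H6", element_rules(mass_range = c(50, 800))))
  r4 <- element_rules(rdbe = c(0, 3))
  expect_equal(attr(check_constraints("C6H6", r4), "reason"), "rdbe")
  expect_equal(rdbe("C6H6"), 4)
  expect_equal(rdbe("C6H12O6"), 1)
})
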