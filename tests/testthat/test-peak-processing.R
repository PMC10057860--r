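# Window stitching, noise filtering, alignment, blank/IS/QC handling.

test_that("overlap peaks are kept once, from the window past the midpoint", {
  scheme <- window_scheme(c(225, 305), c(315, 355))
  p1 <- data.frame(mz = c(250, 310, 312), intensity = c(1, 2, 3))
  p2 <- data.frame(mz = c(310, 312, 340), intensity = c(2, 3, 4))
  out <- stitch_windows(list(p1, p2), scheme)
  # overlap [305, 315], midpoint 310: 310 and 312 come from window 2 only
  expect_equal(out$mz, c(250, 310, 312, 340))
  expect_equal(sum(out$mz == 310), 1L)
})

test_that("non-overlapping windows concatenate sorted; empties are empty", {
  scheme <- window_scheme(c(100, 300), c(200, 400))
  p1 <- data.frame(mz = c(150, 120), intensity = c(1, 2))
  p2 <- data.frame(mz = 350, intensity = 3)
  out <- stitch_windows(list(p1, p2), scheme)
  expect_equal(out$mz, c(120, 150, 350))
  empty <- stitch_windows(list(p1[0, ], p2[0, ]), scheme)
  expect_equal(nrow(empty), 0L)
  expect_error(stitch_windows(list(data.frame(mz = 250, intensity = 1),
                                   p2[0, ]), scheme),
               "outside its declared window")
})

test_that("stitching equals a brute-force overlap dedup oracle", {
  set.seed(71)
  scheme <- default_window_scheme()
  truth_mz <- runif(400, 66, 608)
  scans <- lapply(seq_len(nrow(scheme)), function(w) {
    keep <- truth_mz >= scheme$low[w] & truth_mz <= scheme$high[w]
    data.frame(mz = truth_mz[keep], intensity = 1)
  })
  out <- stitch_windows(scans, scheme)
  # oracle: each distinct peak must appear exactly once
  expect_equal(sort(out$mz), sort(unique(truth_mz)))
})

test_that("the S/N filter is strictly greater-than", {
  p <- data.frame(mz = c(100, 101, 102), intensity = 1, snr = c(5, 10, 11))
  expect_equal(filter_noise(p, 10)$snr, 11)
  expect_equal(filter_noise(p, 0)$snr, c(5, 10, 11))
  expect_equal(nrow(filter_noise(p[0, ], 10)), 0L)
  expect_error(filter_noise(data.frame(mz = 1, intensity = 1), 10), "snr")
})

test_that("alignment merges within tolerance and splits beyond it", {
  s1 <- data.frame(mz = 200.0000, intensity = 100)
  s2 <- data.frame(mz = 200.0005, intensity = 200) # 2.5 ppm apart
  ft <- align_peaks(list(a = s1, b = s2), tol_ppm = 5)
  expect_equal(n_features(ft), 1L)
  expect_equal(ft$intensity[1, ], c(a = 100, b = 200))
  # weighted consensus m/z lies between the two
  expect_true(ft$mz > 200 && ft$mz < 200.0005)
  s3 <- data.frame(mz = 200.010, intensity = 50) # 50 ppm apart
  ft2 <- align_peaks(list(a = s1, b = s3), tol_ppm = 5)
  expect_equal(n_features(ft2), 2L)
  # a single sample maps to itself
  ft3 <- align_peaks(list(a = data.frame(mz = c(100, 200), intensity = 1)))
  expect_equal(ft3$mz, c(100, 200))
})

test_that("alignment is sample-order invariant and bounded by peak count", {
  set.seed(72)
  samples <- lapply(1:4, function(i)
    data.frame(mz = sort(runif(60, 100, 600)), intensity = rlnorm(60, 8)))
  names(samples) <- paste0("s", 1:4)
  ft1 <- align_peaks(samples, tol_ppm = 5)
  ft2 <- align_peaks(rev(samples), tol_ppm = 5)
  expect_equal(ft1$mz, ft2$mz)
  expect_equal(ft1$intensity[, names(samples)],
               ft2$intensity[, names(samples)])
  expect_lte(n_features(ft1), sum(vapply(samples, nrow, integer(1))))
  expect_false(is.unsorted(ft1$mz, strictly = TRUE))
})

mk_ft <- function(int, roles) {
  ft <- align_peaks(lapply(seq_len(ncol(int)), function(j)
    data.frame(mz = seq(100, by = 10, length.out = nrow(int)),
               intensity = int[, j])), tol_ppm = 1)
  names(ft$roles) <- names(roles)
  ft$roles[] <- roles
  ft$samples <- names(ft$roles)
  colnames(ft$intensity) <- names(ft$roles)
  ft
}

test_that("blank reduction keeps features at or above the fold ratio", {
  int <- cbind(s1 = c(300, 100, 50), b1 = c(100, 100, 0))
  ft <- mk_ft(int, c(s1 = "sample", b1 = "blank"))
  out <- blank_reduction(ft, ratio_min = 3)
  # 300 >= 3*100 kept; 100 < 3*100 removed; blank-absent kept
  expect_equal(out$intensity[, "s1"], c(300, 50))
  expect_error(blank_reduction(mk_ft(cbind(s1 = 1), c(s1 = "sample"))),
               "blank")
})

test_that("IS normalization divides by the matched standard per sample", {
  int <- cbind(s1 = c(1000, 500), s2 = c(2000, 1000))
  ft <- mk_ft(int, c(s1 = "sample", s2 = "sample"))
  # feature 2 (m/z 110) is the IS
  out <- normalize_by_is(ft, is_mz = 110, tol_ppm = 10)
  expect_equal(out$intensity[1, ], c(s1 = 2, s2 = 2))
  expect_equal(out$intensity[2, ], c(s1 = 1, s2 = 1))
  # rescaling one sample's raw intensities leaves normalized values fixed
  ft2 <- ft; ft2$intensity[, "s2"] <- ft$intensity[, "s2"] * 7
  out2 <- normalize_by_is(ft2, is_mz = 110, tol_ppm = 10)
  expect_equal(out2$intensity, out$intensity)
  # an IS missing from one sample is an error naming the culprit
  ft3 <- ft; ft3$intensity[2, "s2"] <- 0
  expect_error(normalize_by_is(ft3, is_mz = 110, tol_ppm = 10), "s2")
  expect_error(normalize_by_is(ft, is_mz = 400, tol_ppm = 10), "not found")
})

test_that("the QC RSD filter uses sample sd over mean in percent", {
  int <- cbind(q1 = c(100, 100), q2 = c(100, 200), q3 = c(100, 150))
  ft <- mk_ft(int, c(q1 = "qc", q2 = "qc", q3 = "qc"))
  out <- rsd_qc_filter(ft, rsd_max = 30)
  # feature 1: RSD 0 retained; feature 2: sd/mean = 50/150 = 33.3% removed
  expect_equal(n_features(out), 1L)
  expect_equal(attr(out, "rsd"), 0)
  # two-point case from hand arithmetic: sd(100,200)/150 = 47.1%
  ft2 <- mk_ft(cbind(q1 = 100, q2 = 200), c(q1 = "qc", q2 = "qc"))
  expect_equal(n_features(rsd_qc_filter(ft2, 30)), 0L)
  expect_equal(n_features(rsd_qc_filter(ft2, 48)), 1L)
  # scale invariance
  ft3 <- mk_ft(int * 1000, c(q1 = "qc", q2 = "qc", q3 = "qc"))
  expect_equal(n_features(rsd_qc_filter(ft3, 30)), 1L)
  expect_error(rsd_qc_filter(mk_ft(cbind(q1 = 1), c(q1 = "qc"))), "2 QC")
})

test_that("mzML ingestion pools spectra into one sorted peak list", {
  f <- tempfile(fileext = ".mzML")
  pks <- list(cbind(mz = c(100.1, 200.2), intensity = c(10, 20)),
              cbind(mz = 150.15, intensity = 5))
  hdr <- data.frame(seqNum = 1:2, acquisitionNum = 1:2, msLevel = 1L,
    polarity = 1L, peaksCount = c(2L, 1L), totIonCurrent = c(30, 5),
    retentionTime = c(1, 2), basePeakMZ = c(200.2, 150.15),
    basePeakIntensity = c(20, 5), collisionEnergy = 0,
    ionisationEnergy = 0, lowMZ = c(100.1, 150.15),
    highMZ = c(200.2, 150.15), precursorScanNum = 0L, precursorMZ = 0,
    precursorCharge = 0L, precursorIntensity = 0, mergedScan = 0L,
    mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 0,
    filterString = NA_character_, spectrumId = paste0("scan=", 1:2),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(pks, f, header = hdr)
  p <- read_peaks_mzml(f)
  expect_equal(p$mz, c(100.1, 150.15, 200.2), tolerance = 1e-6)
  expect_equal(p$intensity, c(10, 5, 20))
  expect_true(all(is.infinite(p$snr)))
})

test_that("isotopologue features are flagged and recorded on their parent", {
  pat <- isotope_pattern("C20H30O5", max_shells = 1) # M+1 about 22%
  mono_mz <- ion_mz("C20H30O5", "[M+H]+")
  m1_mz <- mono_mz + (pat$mz[2] - pat$mz[1])
  peaks <- data.frame(mz = c(mono_mz, m1_mz, 500.0),
                      intensity = c(1e5, 1e5 * pat$rel_intensity[2], 5e4))
  ft <- align_peaks(list(s1 = peaks), tol_ppm = 5)
  ft <- flag_isotopologues(ft)
  expect_equal(ft$monoisotopic, c(TRUE, FALSE, TRUE))
  expect_equal(ft$m1_mz[1], m1_mz, tolerance = 1e-6)
  expect_equal(ft$m1_ratio[1], pat$rel_intensity[2], tolerance = 1e-6)
  feats <- features_for_assignment(ft)
  expect_equal(nrow(feats), 2L)
})
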