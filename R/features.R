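# Cross-sample feature tables: alignment, blank reduction, IS
# normalization, QC filtering and monoisotopic-feature selection.

.new_feature_table <- function(mz, intensity, roles,
                               m1_mz = NULL, m1_ratio = NULL,
                               monoisotopic = NULL, normalized = FALSE) {
  n <- length(mz)
  structure(list(
    mz = mz,
    intensity = intensity,
    samples = colnames(intensity),
    roles = roles,
    m1_mz = if (is.null(m1_mz)) rep(NA_real_, n) else m1_mz,
    m1_ratio = if (is.null(m1_ratio)) rep(NA_real_, n) else m1_ratio,
    monoisotopic = if (is.null(monoisotopic)) rep(NA, n) else monoisotopic,
    normalized = normalized), class = "feature_table")
}

.ft_subset <- function(ft, keep) {
  ft$mz <- ft$mz[keep]
  ft$intensity <- ft$intensity[keep, , drop = FALSE]
  ft$m1_mz <- ft$m1_mz[keep]
  ft$m1_ratio <- ft$m1_ratio[keep]
  ft$monoisotopic <- ft$monoisotopic[keep]
  ft
}

#' Number of features
#' @param ft A `feature_table`.
#' @return Integer count.
#' @export
n_features <- function(ft) length(ft$mz)

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table: ", n_features(x), " features x ",
      length(x$samples), " samples (", sum(x$roles == "sample"), " sample, ",
      sum(x$roles == "blank"), " blank, ", sum(x$roles == "qc"), " qc)\n",
      sep = "")
  if (any(!is.na(x$monoisotopic)))
    cat("  monoisotopic: ", sum(x$monoisotopic, na.rm = TRUE), "\n")
  if (x$normalized) cat("  IS-normalized\n")
  invisible(x)
}

#' Align peaks across samples into consensus features
#'
#' Greedy single-linkage clustering in ascending m/z: peaks from all
#' samples are pooled and sorted; a peak joins the current cluster iff it
#' lies within `tol_ppm` of the cluster's running intensity-weighted mean
#' m/z, otherwise it starts a new cluster. Each sample contributes at most
#' its most intense peak per cluster. Deterministic and standard for
#' direct-infusion data, where there is no retention-time axis.
#'
#' @param samples Named list of peak data.frames (columns `mz`,
#'   `intensity`).
#' @param tol_ppm Alignment tolerance in ppm (default 5).
#' @param roles Named character vector mapping sample names to
#'   `sample`/`blank`/`qc`; defaults to all `"sample"`.
#' @return A `feature_table` with consensus m/z in strictly increasing
#'   order and one intensity column per sample (0 when absent).
#' @export
align_peaks <- function(samples, tol_ppm = 5, roles = NULL) {
  stopifnot(tol_ppm > 0, length(samples) >= 1L)
  if (is.null(names(samples)))
    names(samples) <- paste0("S", seq_along(samples))
  if (is.null(roles))
    roles <- stats::setNames(rep("sample", length(samples)), names(samples))
  roles <- roles[names(samples)]
  mz <- unlist(lapply(samples, function(p) p$mz), use.names = FALSE)
  intensity <- unlist(lapply(samples, function(p) p$intensity),
                      use.names = FALSE)
  src <- rep(seq_along(samples),
             vapply(samples, nrow, integer(1)))
  if (length(mz) == 0L)
    return(.new_feature_table(numeric(0),
                              matrix(0, 0, length(samples),
                                     dimnames = list(NULL, names(samples))),
                              roles))
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]; src <- src[o]
  cluster <- integer(length(mz))
  cl <- 1L
  wsum <- intensity[1L]
  msum <- mz[1L] * intensity[1L]
  cluster[1L] <- 1L
  for (i in seq_along(mz)[-1L]) {
    mean_mz <- if (wsum > 0) msum / wsum else mz[i - 1L]
    if ((mz[i] - mean_mz) / mean_mz * 1e6 <= tol_ppm) {
      cluster[i] <- cl
      wsum <- wsum + intensity[i]
      msum <- msum + mz[i] * intensity[i]
    } else {
      cl <- cl + 1L
      cluster[i] <- cl
      wsum <- intensity[i]
      msum <- mz[i] * intensity[i]
    }
  }
  n_cl <- cl
  imat <- matrix(0, n_cl, length(samples),
                 dimnames = list(NULL, names(samples)))
  cons <- numeric(n_cl)
  for (k in seq_len(n_cl)) {
    idx <- which(cluster == k)
    w <- intensity[idx]
    cons[k] <- if (sum(w) > 0) sum(mz[idx] * w) / sum(w) else mean(mz[idx])
    for (i in idx)
      imat[k, src[i]] <- max(imat[k, src[i]], intensity[i])
  }
  .new_feature_table(cons, imat, roles)
}

.role_means <- function(ft, role) {
  cols <- which(ft$roles == role)
  if (length(cols) == 0L) return(NULL)
  rowMeans(ft$intensity[, cols, drop = FALSE])
}

#' Blank reduction
#'
#' Retains features whose mean intensity across biological samples is at
#' least `ratio_min` times the mean across blank samples; features absent
#' from all blanks are always retained.
#'
#' @param ft A `feature_table` containing at least one blank sample.
#' @param ratio_min Minimum sample/blank fold ratio (default 3).
#' @return Filtered `feature_table`.
#' @export
blank_reduction <- function(ft, ratio_min = 3) {
  blank <- .role_means(ft, "blank")
  if (is.null(blank)) stop("no blank samples in the feature table")
  samp <- .role_means(ft, "sample")
  if (is.null(samp)) samp <- .role_means(ft, "qc")
  keep <- blank == 0 | samp >= ratio_min * blank
  .ft_subset(ft, keep)
}

#' Internal-standard normalization
#'
#' Divides each feature's intensity by the intensity of its mapped
#' internal standard (IS) in the same sample. Each IS m/z must match a
#' feature present in every sample; by default each feature is mapped to
#' the IS nearest in m/z.
#'
#' @param ft A `feature_table`.
#' @param is_mz Numeric vector of IS ion m/z values.
#' @param tol_ppm Tolerance for locating each IS among the features
#'   (default 5 ppm).
#' @return Normalized `feature_table` (`normalized = TRUE`).
#' @export
normalize_by_is <- function(ft, is_mz, tol_ppm = 5) {
  stopifnot(length(is_mz) >= 1L)
  is_idx <- vapply(is_mz, function(m) {
    d <- abs(ft$mz - m) / m * 1e6
    i <- which.min(d)
    if (length(i) == 0L || d[i] > tol_ppm)
      stop("internal standard at m/z ", m,
           " not found among features within ", tol_ppm, " ppm")
    i
  }, integer(1))
  is_int <- ft$intensity[is_idx, , drop = FALSE]
  for (j in seq_along(ft$samples)) {
    zero <- is_int[, j] <= 0
    if (any(zero))
      stop("internal standard at m/z ", is_mz[which(zero)[1L]],
           " missing from sample '", ft$samples[j], "'")
  }
  map <- vapply(ft$mz, function(m) which.min(abs(is_mz - m)), integer(1))
  ft$intensity <- ft$intensity / is_int[map, , drop = FALSE]
  ft$normalized <- TRUE
  ft
}

#' QC repeatability (RSD) filter
#'
#' Computes each feature's relative standard deviation over the QC
#' replicates (`100 * sd / mean`, sample sd) and retains features with
#' RSD strictly below `rsd_max`. Features absent from the QCs (mean 0 or
#' undefined RSD) are removed.
#'
#' @param ft A `feature_table` with at least two QC samples.
#' @param rsd_max Maximum RSD in percent (default 30).
#' @return Filtered `feature_table`; the retained RSDs are attached as
#'   attribute `"rsd"`.
#' @export
rsd_qc_filter <- function(ft, rsd_max = 30) {
  qc <- which(ft$roles == "qc")
  if (length(qc) < 2L) stop("RSD filtering requires at least 2 QC samples")
  q <- ft$intensity[, qc, drop = FALSE]
  m <- rowMeans(q)
  s <- apply(q, 1L, stats::sd)
  rsd <- ifelse(m > 0, 100 * s / m, NA_real_)
  keep <- !is.na(rsd) & rsd < rsd_max
  out <- .ft_subset(ft, keep)
  attr(out, "rsd") <- rsd[keep]
  out
}

#' Flag isotopologue (non-monoisotopic) features
#'
#' A feature is flagged non-monoisotopic when another feature exists one
#' 13C-12C mass unit below it (within `tol_ppm`) whose intensity makes the
#' upper feature a plausible M+1 partner: the observed intensity ratio must
#' not exceed `slack` times the largest M+1 fraction a CHNOPS formula of
#' that mass could have (all-carbon skeleton, 1.07% per carbon). Flagged
#' features are excluded from assignment; their m/z and intensity ratio are
#' recorded on the monoisotopic partner and feed the isotope-similarity
#' score.
#'
#' @param ft A `feature_table`.
#' @param tol_ppm Matching tolerance (default 2 ppm).
#' @param slack Multiplier on the maximum plausible M+1 fraction
#'   (default 1.5).
#' @return `feature_table` with `monoisotopic`, `m1_mz` and `m1_ratio`
#'   filled in.
#' @export
flag_isotopologues <- function(ft, tol_ppm = 2, slack = 1.5) {
  n <- n_features(ft)
  mono <- rep(TRUE, n)
  m1_mz <- rep(NA_real_, n)
  m1_ratio <- rep(NA_real_, n)
  mean_int <- rowMeans(ft$intensity)
  rate <- .M1_RATE$rate[["C"]]
  for (i in seq_len(n)) {
    target <- ft$mz[i] - ISO_UNIT
    if (target <= 0) next
    d <- abs(ft$mz - target) / ft$mz[i] * 1e6
    j <- which.min(d)
    if (d[j] > tol_ppm || j == i) next
    if (mean_int[j] <= 0) next
    ratio <- mean_int[i] / mean_int[j]
    max_plausible <- slack * rate * floor(ft$mz[j] / ELEMENT_MASS[["C"]])
    if (ratio <= max_plausible) {
      mono[i] <- FALSE
      m1_mz[j] <- ft$mz[i]
      m1_ratio[j] <- ratio
    }
  }
  ft$monoisotopic <- mono
  ft$m1_mz <- m1_mz
  ft$m1_ratio <- m1_ratio
  ft
}

#' Extract monoisotopic features for assignment
#'
#' @param ft A `feature_table` (after [flag_isotopologues()]; if flags are
#'   missing, all features are used).
#' @return Data.frame with `feature_id`, `mz`, `m1_mz`, `m1_ratio`,
#'   `mean_intensity`.
#' @export
features_for_assignment <- function(ft) {
  keep <- if (all(is.na(ft$monoisotopic))) rep(TRUE, n_features(ft))
          else ft$monoisotopic
  data.frame(feature_id = which(keep), mz = ft$mz[keep],
             m1_mz = ft$m1_mz[keep], m1_ratio = ft$m1_ratio[keep],
             mean_intensity = rowMeans(ft$intensity)[keep])
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  data.frame(feature_id = seq_along(x$mz), mz = x$mz,
             m1_mz = x$m1_mz, m1_ratio = x$m1_ratio,
             monoisotopic = x$monoisotopic, x$intensity,
             check.names = FALSE)
}

#' Write / read a feature table as CSV
#'
#' The CSV holds the meta columns (`feature_id`, `mz`, `m1_mz`,
#' `m1_ratio`, `monoisotopic`) followed by one intensity column per
#' sample. Roles are written to a companion `<path>.roles.csv`.
#'
#' @param ft A `feature_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  utils::write.csv(as.data.frame(ft), path, row.names = FALSE)
  utils::write.csv(data.frame(sample = names(ft$roles), role = ft$roles),
                   paste0(path, ".roles.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("feature_id", "mz", "m1_mz", "m1_ratio", "monoisotopic")
  samp <- setdiff(names(df), meta)
  roles_path <- paste0(path, ".roles.csv")
  roles <- if (file.exists(roles_path)) {
    r <- utils::read.csv(roles_path)
    stats::setNames(r$role, r$sample)[samp]
  } else stats::setNames(rep("sample", length(samp)), samp)
  imat <- as.matrix(df[, samp, drop = FALSE])
  .new_feature_table(df$mz, imat, roles, m1_mz = df$m1_mz,
                     m1_ratio = df$m1_ratio, monoisotopic = df$monoisotopic)
}
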