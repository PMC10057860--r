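# Per-window centroid peak handling: spectral-stitching window merge and
# signal-to-noise filtering.

#' Acquisition window scheme
#'
#' Ordered list of (low, high) m/z acquisition windows; adjacent windows
#' may overlap (spectral stitching acquires narrow windows separately to
#' boost dynamic range and merges them afterwards).
#'
#' @param low,high Numeric vectors of window bounds (Th).
#' @return A data.frame of class `window_scheme` with columns `low`, `high`.
#' @export
window_scheme <- function(low, high) {
  stopifnot(length(low) == length(high), all(high > low),
            !is.unsorted(low))
  structure(data.frame(low = low, high = high),
            class = c("window_scheme", "data.frame"))
}

#' Default spectral-stitching window scheme
#'
#' The nine overlapping positive-mode acquisition windows spanning
#' m/z 65-609 used for serum DI-nESI-HRMS.
#'
#' @return A [window_scheme()].
#' @export
default_window_scheme <- function() {
  window_scheme(low  = c(65, 225, 305, 345, 385, 425, 465, 505, 552),
                high = c(235, 315, 355, 395, 435, 475, 515, 562, 609))
}

#' Merge per-window scans into one peak list
#'
#' In the overlap between consecutive windows each peak is taken from
#' exactly one window, with the boundary at the overlap midpoint: window i
#' keeps peaks below the midpoint, window i+1 keeps peaks at or above it.
#' This is deterministic, symmetric, and avoids using peaks measured at the
#' edge of a window where mass accuracy degrades.
#'
#' @param scans List of peak data.frames (columns `mz`, `intensity`,
#'   optionally `snr`), one per window, in window order.
#' @param scheme A [window_scheme()] with one row per scan.
#' @return A single peak data.frame sorted by m/z.
#' @export
stitch_windows <- function(scans, scheme) {
  stopifnot(length(scans) == nrow(scheme))
  n <- nrow(scheme)
  # boundary above window i (Inf if disjoint from the next window)
  hi_cut <- rep(Inf, n); lo_cut <- rep(-Inf, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (scheme$high[i] > scheme$low[i + 1L]) {
        mid <- (scheme$low[i + 1L] + scheme$high[i]) / 2
        hi_cut[i] <- mid
        lo_cut[i + 1L] <- mid
      }
    }
  }
  pieces <- vector("list", n)
  for (i in seq_len(n)) {
    p <- scans[[i]]
    if (is.null(p) || nrow(p) == 0L) next
    if (any(p$mz < scheme$low[i] | p$mz > scheme$high[i]))
      stop("peak outside its declared window [", scheme$low[i], ", ",
           scheme$high[i], "]")
    keep <- p$mz >= lo_cut[i] & p$mz < hi_cut[i]
    pieces[[i]] <- p[keep, , drop = FALSE]
  }
  out <- do.call(rbind, pieces)
  if (is.null(out)) out <- data.frame(mz = numeric(), intensity = numeric())
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Signal-to-noise filter
#'
#' Retains peaks with `snr` strictly greater than `snr_min` (the default
#' reproduces the conventional S/N > 10 noise filtration).
#'
#' @param peaks Peak data.frame with an `snr` column.
#' @param snr_min Threshold (default 10); the comparison is strict.
#' @return Filtered peak data.frame.
#' @export
filter_noise <- function(peaks, snr_min = 10) {
  if (is.null(peaks$snr))
    stop("peaks must carry an 'snr' column for noise filtration")
  out <- peaks[peaks$snr > snr_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a centroid peak list
#'
#' CSV/TSV with columns `mz`, `intensity` and optionally `snr`, `window`.
#'
#' @param path File path; the delimiter is sniffed from the header line.
#' @return Peak data.frame.
#' @export
read_peaks <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(df)))
    stop("peak list needs at least columns mz,intensity: ", path)
  if (any(df$mz <= 0) || any(df$intensity < 0))
    stop("invalid peak list (mz must be > 0, intensity >= 0): ", path)
  df
}

#' Read a centroid peak list from an mzML file
#'
#' Optional ingestion path for vendor-converted centroid data; requires
#' the Bioconductor package `mzR`. All spectra in the file are pooled
#' into one peak list (direct-infusion acquisitions have no retention
#' axis worth preserving); S/N is not stored in mzML, so the `snr`
#' column is filled with `Inf` and noise filtering should rely on an
#' intensity threshold upstream.
#'
#' @param path Path to a centroid-mode mzML file.
#' @return Peak data.frame with columns `mz`, `intensity`, `snr`.
#' @export
read_peaks_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package")
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  out <- do.call(rbind, lapply(pk, function(m)
    data.frame(mz = m[, 1], intensity = m[, 2])))
  out <- out[order(out$mz), , drop = FALSE]
  out$snr <- Inf
  rownames(out) <- NULL
  out
}

#' Read a sample manifest
#'
#' CSV with columns `file` and `role` (`sample`, `blank` or `qc`).
#'
#' @param path File path.
#' @param base_dir Directory that relative `file` entries are resolved
#'   against (default: the manifest's own directory).
#' @return Data.frame with columns `file`, `role`, `sample` (basename
#'   without extension).
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("file", "role") %in% names(df)))
    stop("manifest needs columns file,role: ", path)
  bad <- setdiff(unique(df$role), c("sample", "blank", "qc"))
  if (length(bad))
    stop("unknown sample role(s): ", paste(bad, collapse = ", "))
  df$sample <- sub("\\.[^.]*$", "", basename(df$file))
  abs <- file.path(base_dir, df$file)
  df$file <- ifelse(file.exists(df$file), df$file, abs)
  df
}
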