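# Synthetic studies with known ground truth: seed-formula universes grown
# to a requested network density, spectra with ppm-scale mass error,
# isotopologue peaks, noise and contaminant peaks, blanks and QC
# replicates, and mass-matched decoy formulas. Everything any pipeline
# stage consumes can be generated here, deterministically under a seed.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(seed)
    return(code)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# One random plausible metabolite-like formula near mass `target` (Da).
.random_formula <- function(target, rules) {
  for (try in seq_len(60L)) {
    c_n <- max(1L, stats::rpois(1L, target / 19))
    o_n <- stats::rpois(1L, 0.35 * c_n)
    n_n <- stats::rpois(1L, 0.15 * c_n)
    p_n <- stats::rbinom(1L, 1L, 0.06)
    s_n <- stats::rbinom(1L, 1L, 0.06)
    fm <- .empty_counts(1L)
    fm[1L, ] <- c(c_n, 0L, n_n, o_n, p_n, s_n)
    rest <- as.numeric(fm %*% ELEMENT_MASS)
    h_n <- round((target - rest) / ELEMENT_MASS[["H"]])
    if (is.na(h_n) || h_n < 0L) next
    fm[1L, "H"] <- as.integer(h_n)
    if (check_constraints(fm, rules)) return(fm)
  }
  NULL
}

#' Generate a seed-formula universe
#'
#' Grows a universe of valid CHNOPS formulas whose induced reaction
#' network has approximately a requested mean degree. Growth mixes three
#' proposal moves under a feedback rule (grow while the running mean
#' degree 2E/V is below `connectivity`, otherwise add an unrelated random
#' formula): a random formula at a uniform target mass; a reaction step
#' from an existing member; and a "densify" step that completes a lattice
#' square by applying two of a member's incident reaction differences in
#' sequence, which is what pushes the density beyond the tree limit of
#' mean degree 2.
#'
#' @param n Number of formulas (>= 2).
#' @param mass_range Neutral mass bounds (Da).
#' @param connectivity Target mean degree of the induced network
#'   (default 10, the density scale of the curated endogenous-metabolite
#'   networks); 0 yields an essentially edge-free universe.
#' @param reactions Reaction table.
#' @param rules [element_rules()].
#' @param seed RNG seed (the same seed reproduces the universe exactly).
#' @return Character vector of `n` distinct formulas, with the induced
#'   edge list as attribute `"edges"`.
#' @export
make_seed_universe <- function(n, mass_range = c(50, 800), connectivity = 10,
                               reactions = default_reactions(),
                               rules = element_rules(), seed = NULL) {
  stopifnot(n >= 2L, connectivity >= 0)
  .with_seed(seed, {
    diffs <- reaction_diffs(reactions)
    counts <- .empty_counts(n)
    keys <- new.env(hash = TRUE, parent = emptyenv())
    nbrs <- vector("list", n)
    edges_from <- integer(0); edges_to <- integer(0)
    k <- 0L; n_edges <- 0L
    gen_rules <- element_rules(elements = rules$elements,
                               hc_ratio = rules$hc_ratio,
                               mass_range = mass_range)
    add_node <- function(fm) {
      key <- .formula_key(fm)
      if (!is.null(keys[[key]])) return(FALSE)
      k <<- k + 1L
      counts[k, ] <<- fm
      keys[[key]] <- k
      # neighbors among existing nodes
      tgt <- rbind(sweep(diffs, 2L, fm, "+"),
                   sweep(-diffs, 2L, fm, "+"))
      tkeys <- .formula_key(tgt)
      hits <- unique(unlist(mget(tkeys, envir = keys,
                                 ifnotfound = list(NULL)),
                            use.names = FALSE))
      hits <- setdiff(hits, k)
      if (length(hits)) {
        edges_from <<- c(edges_from, rep(k, length(hits)))
        edges_to <<- c(edges_to, hits)
        n_edges <<- n_edges + length(hits)
        nbrs[[k]] <<- hits
        for (j in hits) nbrs[[j]] <<- c(nbrs[[j]], k)
      }
      TRUE
    }
    # metabolite-like mass profile: most formulas in the low hundreds of
    # Da, with a thinning high-mass tail (truncated lognormal)
    draw_mass <- function() {
      for (i in seq_len(50L)) {
        m <- stats::rlnorm(1L, meanlog = log(280), sdlog = 0.45)
        if (m >= mass_range[1] && m <= mass_range[2]) return(m)
      }
      stats::runif(1L, mass_range[1], mass_range[2])
    }
    propose_random <- function() .random_formula(draw_mass(), gen_rules)
    propose_grow <- function() {
      i <- sample.int(k, 1L)
      d <- diffs[sample.int(nrow(diffs), 1L), ]
      fm <- .empty_counts(1L)
      fm[1L, ] <- counts[i, ] + sample(c(1L, -1L), 1L) * d
      if (any(fm < 0L) || !check_constraints(fm, gen_rules)) return(NULL)
      fm
    }
    propose_densify <- function() {
      deg2 <- which(lengths(nbrs[seq_len(k)]) >= 2L)
      if (!length(deg2)) return(propose_grow())
      i <- deg2[sample.int(length(deg2), 1L)]
      nb <- sample(nbrs[[i]], 2L)
      d12 <- counts[nb[1L], ] + counts[nb[2L], ] - 2 * counts[i, ]
      if (all(d12 == 0L)) return(NULL)
      fm <- .empty_counts(1L)
      fm[1L, ] <- counts[i, ] + d12
      if (any(fm < 0L) || !check_constraints(fm, gen_rules)) return(NULL)
      fm
    }
    # a small fixed fraction of formulas are network orphans (compounds
    # with no tabulated reaction partner); the rest are reaction-derived,
    # with the feedback rule switching between single-step growth and
    # lattice-completing densification to hold the mean degree near the
    # requested connectivity
    p_orphan <- 0.05
    guard <- 0L
    while (k < n) {
      guard <- guard + 1L
      if (guard > 200L * n)
        stop("could not grow a universe of ", n,
             " formulas with the requested connectivity")
      mean_deg <- if (k > 0L) 2 * n_edges / k else 0
      fm <- if (k < 2L || connectivity == 0 ||
                stats::runif(1L) < p_orphan) {
        propose_random()
      } else if (mean_deg < connectivity) {
        # densification raises density; interleaved growth keeps supplying
        # fresh frontier nodes for future densification moves
        if (stats::runif(1L) < 0.75) propose_densify() else propose_grow()
      } else {
        propose_grow()
      }
      if (!is.null(fm)) add_node(fm)
    }
    out <- format_formula(counts)
    attr(out, "edges") <- data.frame(from = edges_from, to = edges_to)
    out
  })
}

#' Generate mass-matched decoy formulas
#'
#' Valid formulas absent from an exclusion universe, with masses drawn
#' from the universe's own mass distribution (each decoy is generated at
#' the mass of a randomly sampled universe member), so that decoys are
#' plausible-but-false entries for target-decoy evaluation.
#'
#' @param n Number of decoys.
#' @param universe Character vector of formulas to exclude.
#' @param rules [element_rules()].
#' @param seed RNG seed.
#' @return Character vector of `n` distinct decoy formulas.
#' @export
make_decoys <- function(n, universe, rules = element_rules(), seed = NULL) {
  stopifnot(n >= 1L)
  .with_seed(seed, {
    excl <- new.env(hash = TRUE, parent = emptyenv())
    for (key in .formula_key(parse_formula(universe))) excl[[key]] <- TRUE
    masses <- monoisotopic_mass(universe)
    out <- character(0)
    guard <- 0L
    while (length(out) < n) {
      guard <- guard + 1L
      if (guard > 500L * n)
        stop("decoy generation exhausted after ", guard, " attempts")
      fm <- .random_formula(sample(masses, 1L), rules)
      if (is.null(fm)) next
      key <- .formula_key(fm)
      if (!is.null(excl[[key]])) next
      excl[[key]] <- TRUE
      out <- c(out, format_formula(fm))
    }
    out
  })
}

#' Simulate one spectrum for a set of truth ions
#'
#' Emits a single sample's centroid peak list: each truth ion at its
#' theoretical m/z perturbed by multiplicative Gaussian ppm error, an M+1
#' isotopologue peak at the predicted relative intensity with lognormal-ish
#' intensity error, and uniform low-intensity noise peaks; the list is
#' split into acquisition windows (peaks in overlap regions appear in both
#' windows, exercising the stitching merge).
#'
#' @param formulas Character vector of truth formulas.
#' @param adducts Adduct label per truth (recycled).
#' @param intensity Monoisotopic intensities (recycled; default 1e5).
#' @param ppm_sd Mass error sd in ppm.
#' @param iso_cv Relative intensity error (CV) of M+1 peaks.
#' @param n_noise Number of noise peaks.
#' @param windows A [window_scheme()].
#' @param seed RNG seed.
#' @return List with `scans` (per-window peak data.frames with columns
#'   `mz`, `intensity`, `snr`) and `truth` (data.frame `formula`,
#'   `adduct`, `mz`).
#' @export
make_spectrum <- function(formulas, adducts = "[M+H]+", intensity = 1e5,
                          ppm_sd = 0.7, iso_cv = 0.2, n_noise = 0L,
                          windows = default_window_scheme(), seed = NULL) {
  stopifnot(ppm_sd >= 0)
  .with_seed(seed, {
    fm <- parse_formula(formulas)
    n <- nrow(fm)
    adducts <- rep_len(adducts, n)
    intensity <- rep_len(intensity, n)
    mz_true <- ion_mz(fm, adducts)
    m1 <- .m1_shell(fm)
    jit <- function(mz) mz * (1 + stats::rnorm(length(mz), 0, ppm_sd * 1e-6))
    m1_int <- intensity * m1$rel_intensity *
      pmax(0, 1 + stats::rnorm(n, 0, iso_cv))
    peaks <- data.frame(
      mz = c(jit(mz_true), jit(mz_true + m1$offset)),
      intensity = c(intensity, m1_int),
      snr = c(intensity, m1_int) / 1e3)
    if (n_noise > 0L) {
      noise_int <- stats::rlnorm(n_noise, log(8e3), 0.7)
      peaks <- rbind(peaks, data.frame(
        mz = stats::runif(n_noise, min(windows$low), max(windows$high)),
        intensity = noise_int,
        snr = stats::runif(n_noise, 1, 30)))
    }
    scans <- lapply(seq_len(nrow(windows)), function(w) {
      keep <- peaks$mz >= windows$low[w] & peaks$mz <= windows$high[w]
      p <- peaks[keep, , drop = FALSE]
      rownames(p) <- NULL
      p
    })
    list(scans = scans,
         truth = data.frame(formula = format_formula(fm), adduct = adducts,
                            mz = mz_true))
  })
}

# Sample node indices with probability proportional to degree (isolated
# nodes are never drawn): truth metabolites emulate reference standards
# and abundant endogenous compounds, which sit inside known biochemistry.
.degree_weighted_sample <- function(degree, size) {
  sample.int(length(degree), size, replace = FALSE, prob = degree)
}

#' Generate a complete synthetic study
#'
#' Builds a seed universe, draws ground-truth metabolites (a configurable
#' fraction taken from the universe itself, the rest novel formulas one
#' reaction step away from it -- both sampled towards the well-connected
#' core, emulating that reference standards and abundant serum metabolites
#' are common, well-networked compounds), and emits per-window centroid
#' peak lists for biological samples, blanks and QC replicates. Truth ions
#' carry Gaussian ppm mass error and an M+1 isotopologue peak with
#' intensity error; noise peaks, blank contaminants and internal-standard
#' ions exercise the corresponding preprocessing branches.
#'
#' @param n_seeds Universe size (default 2000).
#' @param n_truth Number of ground-truth metabolites (default 200).
#' @param connectivity Target mean degree of the universe network
#'   (default 10).
#' @param novel_frac Fraction of truths absent from the universe but
#'   reaction-adjacent to it (default 0.3).
#' @param ppm_sd Mass error sd in ppm (default 0.7; observed DI-HRMS
#'   errors cluster near zero well within a 2 ppm tolerance).
#' @param iso_cv Relative intensity error (CV) of M+1 peaks (default 0.2).
#' @param n_noise Noise peaks per sample (default 500).
#' @param n_contam Blank contaminant ions (default 25).
#' @param n_samples,n_blanks,n_qc Sample layout (defaults 3/2/3).
#' @param bio_cv,qc_cv Intensity CV across biological samples / QC
#'   replicates (defaults 0.3 / 0.05).
#' @param adducts Adduct labels truths are ionized with (one drawn per
#'   truth).
#' @param windows Acquisition [window_scheme()] (default
#'   [default_window_scheme()]); truth ions are constrained to fall inside
#'   it.
#' @param reactions Reaction table.
#' @param rules [element_rules()].
#' @param seed RNG seed; the same seed reproduces the study exactly.
#' @return An object of class `synthetic_study`: list with `universe`,
#'   `truth` (data.frame `formula`, `adduct`, `mz`, `in_universe`,
#'   `intensity`), `scans` (per sample: list of per-window peak
#'   data.frames), `roles`, `is_mz`, `windows`, `decoys = NULL` (generate
#'   separately), and `params`.
#' @export
make_study <- function(n_seeds = 2000L, n_truth = 200L, connectivity = 10,
                       novel_frac = 0.3, ppm_sd = 0.7, iso_cv = 0.2,
                       n_noise = 500L, n_contam = 25L,
                       n_samples = 3L, n_blanks = 2L, n_qc = 3L,
                       bio_cv = 0.3, qc_cv = 0.05,
                       adducts = names(ADDUCT_MASS),
                       windows = default_window_scheme(),
                       reactions = default_reactions(),
                       rules = element_rules(), seed = NULL) {
  stopifnot(ppm_sd >= 0, n_truth >= 1L)
  .with_seed(seed, {
    universe <- make_seed_universe(n_seeds, mass_range = rules$mass_range,
                                   connectivity = connectivity,
                                   reactions = reactions, rules = rules)
    ucounts <- parse_formula(universe)
    uedges <- attr(universe, "edges")
    degree <- tabulate(c(uedges$from, uedges$to), nbins = n_seeds)
    ukeys <- .formula_key(ucounts)
    diffs <- reaction_diffs(reactions)
    mz_lo <- min(windows$low); mz_hi <- max(windows$high)

    truth_rules <- element_rules(elements = rules$elements,
                                 hc_ratio = rules$hc_ratio,
                                 mass_range = rules$mass_range)
    pick_adduct <- function() sample(adducts, 1L)
    n_novel <- round(novel_frac * n_truth)
    n_in <- n_truth - n_novel

    # in-universe truths: degree-weighted draw, ion must land in a window
    truth_fm <- .empty_counts(0L)
    truth_ad <- character(0); truth_in <- logical(0)
    connected_nodes <- which(degree > 0)
    cand_order <- connected_nodes[
      .degree_weighted_sample(degree[connected_nodes],
                              length(connected_nodes))]
    for (i in cand_order) {
      if (nrow(truth_fm) >= n_in) break
      ad <- pick_adduct()
      mz <- ion_mz(ucounts[i, , drop = FALSE], ad)
      if (mz < mz_lo || mz > mz_hi) next
      truth_fm <- rbind(truth_fm, ucounts[i, , drop = FALSE])
      truth_ad <- c(truth_ad, ad); truth_in <- c(truth_in, TRUE)
    }
    # novel truths: unknown metabolites embedded in metabolic families --
    # a double modification x + d1 + d2 of a universe member x whose
    # single-modification relatives x + d1 and x + d2 are both known, so
    # every novel truth is reaction-adjacent to the universe (degree >= 2
    # by construction, like real unassigned serum metabolites that are
    # acylated/hydroxylated/conjugated variants of known compounds)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (key in c(ukeys, .formula_key(truth_fm))) seen[[key]] <- TRUE
    adj <- vector("list", n_seeds)
    for (r in seq_len(nrow(uedges))) {
      adj[[uedges$from[r]]] <- c(adj[[uedges$from[r]]], uedges$to[r])
      adj[[uedges$to[r]]] <- c(adj[[uedges$to[r]]], uedges$from[r])
    }
    deg2_nodes <- which(lengths(adj) >= 2L)
    guard <- 0L
    while (sum(!truth_in) < n_novel) {
      guard <- guard + 1L
      if (guard > 500L * n_novel)
        stop("could not draw enough novel reaction-neighbor truths")
      i <- deg2_nodes[.degree_weighted_sample(degree[deg2_nodes], 1L)]
      nb <- sample(adj[[i]], 2L)
      fm <- .empty_counts(1L)
      fm[1L, ] <- ucounts[nb[1L], ] + ucounts[nb[2L], ] - ucounts[i, ]
      if (any(fm < 0L) || !check_constraints(fm, truth_rules)) next
      key <- .formula_key(fm)
      if (!is.null(seen[[key]])) next
      ad <- pick_adduct()
      mz <- ion_mz(fm, ad)
      if (mz < mz_lo || mz > mz_hi) next
      seen[[key]] <- TRUE
      truth_fm <- rbind(truth_fm, fm)
      truth_ad <- c(truth_ad, ad); truth_in <- c(truth_in, FALSE)
    }
    n_truth_eff <- nrow(truth_fm)
    truth <- data.frame(formula = format_formula(truth_fm),
                        adduct = truth_ad,
                        mz = ion_mz(truth_fm, truth_ad),
                        in_universe = truth_in,
                        intensity = stats::rlnorm(n_truth_eff,
                                                  meanlog = log(1e5),
                                                  sdlog = 0.8))
    # theoretical M+1 shells of the truths
    m1 <- .m1_shell(truth_fm)

    # internal standards: three stable ions spread over the mass range
    is_formula <- c("C9H11NO2", "C11H12N2O2", "C24H40O5") # Phe, Trp, CA-like
    is_mz <- ion_mz(is_formula, "[M+H]+")
    is_int <- c(2e5, 1.5e5, 1e5)

    # blank contaminants: random ions present in blanks and samples alike
    contam_mz <- stats::runif(n_contam, mz_lo, mz_hi)
    contam_int <- stats::rlnorm(n_contam, log(5e4), 0.5)

    roles <- c(rep("sample", n_samples), rep("blank", n_blanks),
               rep("qc", n_qc))
    names(roles) <- sprintf("%s%02d", c(rep("S", n_samples),
                                        rep("B", n_blanks),
                                        rep("Q", n_qc)),
                            c(seq_len(n_samples), seq_len(n_blanks),
                              seq_len(n_qc)))

    jitter_mz <- function(mz) mz * (1 + stats::rnorm(length(mz), 0, ppm_sd * 1e-6))
    split_windows <- function(peaks) {
      lapply(seq_len(nrow(windows)), function(w) {
        keep <- peaks$mz >= windows$low[w] & peaks$mz <= windows$high[w]
        p <- peaks[keep, , drop = FALSE]
        rownames(p) <- NULL
        p
      })
    }

    scans <- lapply(names(roles), function(sn) {
      role <- roles[[sn]]
      pieces <- list()
      if (role != "blank") {
        cv <- if (role == "qc") qc_cv else bio_cv
        ints <- truth$intensity *
          pmax(0.05, 1 + stats::rnorm(n_truth_eff, 0, cv))
        mono_mz <- jitter_mz(truth$mz)
        snr <- ints / 1e3
        m1_int <- ints * m1$rel_intensity *
          pmax(0, 1 + stats::rnorm(n_truth_eff, 0, iso_cv))
        m1_mz <- jitter_mz(truth$mz + m1$offset)
        pieces$truth <- data.frame(
          mz = c(mono_mz, m1_mz), intensity = c(ints, m1_int),
          snr = c(snr, m1_int / 1e3))
      }
      # contaminants appear in blanks and, at similar level, in samples
      pieces$contam <- data.frame(
        mz = jitter_mz(contam_mz),
        intensity = contam_int * pmax(0.05, 1 + stats::rnorm(n_contam, 0, 0.2)),
        snr = contam_int / 1e3)
      pieces$is <- data.frame(
        mz = jitter_mz(is_mz),
        intensity = is_int * pmax(0.05, 1 + stats::rnorm(3L, 0, 0.05)),
        snr = is_int / 1e3)
      noise_int <- stats::rlnorm(n_noise, log(8e3), 0.7)
      pieces$noise <- data.frame(
        mz = stats::runif(n_noise, mz_lo, mz_hi),
        intensity = noise_int,
        snr = stats::runif(n_noise, 1, 30))
      peaks <- do.call(rbind, pieces)
      peaks <- peaks[peaks$mz >= mz_lo & peaks$mz <= mz_hi, , drop = FALSE]
      split_windows(peaks)
    })
    names(scans) <- names(roles)

    structure(list(universe = as.character(universe), truth = truth,
                   scans = scans, roles = roles, is_mz = is_mz,
                   windows = windows,
                   params = list(n_seeds = n_seeds, n_truth = n_truth_eff,
                                 connectivity = connectivity,
                                 novel_frac = novel_frac, ppm_sd = ppm_sd,
                                 iso_cv = iso_cv, n_noise = n_noise,
                                 seed = seed)),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic DI-HRMS study\n")
  cat("  universe:", length(x$universe), "seed formulas\n")
  cat("  truths:  ", nrow(x$truth), " (", sum(!x$truth$in_universe),
      " novel reaction-neighbors)\n", sep = "")
  cat("  samples: ", paste(names(table(x$roles)),
                           table(x$roles), collapse = ", "), "\n")
  invisible(x)
}

#' Run the preprocessing pipeline on a synthetic study
#'
#' Stitches each sample's windows, applies the S/N filter, aligns samples
#' into a feature table, removes blank-derived features, normalizes by the
#' internal standards, applies the QC RSD filter and flags isotopologues.
#'
#' @param study A [make_study()] object.
#' @param snr_min,tol_align_ppm,blank_ratio,rsd_max Pipeline thresholds
#'   (defaults 10, 5 ppm, 3-fold, 30%).
#' @param normalize Apply IS normalization (default TRUE).
#' @return A processed `feature_table`.
#' @export
process_study <- function(study, snr_min = 10, tol_align_ppm = 5,
                          blank_ratio = 3, rsd_max = 30, normalize = TRUE) {
  merged <- lapply(study$scans, function(sc)
    filter_noise(stitch_windows(sc, study$windows), snr_min))
  ft <- align_peaks(merged, tol_ppm = tol_align_ppm, roles = study$roles)
  # ISs are spiked into blanks too, so they must be located and applied
  # before blank reduction would discard them
  if (normalize) ft <- normalize_by_is(ft, study$is_mz)
  ft <- blank_reduction(ft, ratio_min = blank_ratio)
  ft <- rsd_qc_filter(ft, rsd_max = rsd_max)
  flag_isotopologues(ft)
}

#' Write a synthetic study to disk in pipeline input formats
#'
#' Emits per-sample peak-list CSVs (`mz,intensity,snr,window`), a sample
#' manifest, the seed list and the truth table, i.e. exactly the files the
#' preprocessing and assignment entry points consume.
#'
#' @param study A [make_study()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(file = paste0(names(study$roles), ".csv"),
                         role = unname(study$roles))
  for (sn in names(study$scans)) {
    rows <- do.call(rbind, lapply(seq_along(study$scans[[sn]]), function(w) {
      p <- study$scans[[sn]][[w]]
      if (nrow(p) == 0L) return(NULL)
      cbind(p, window = w)
    }))
    utils::write.csv(rows, file.path(dir, paste0(sn, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  writeLines(study$universe, file.path(dir, "seeds.txt"))
  utils::write.csv(study$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(mz = study$is_mz),
                   file.path(dir, "internal_standards.csv"),
                   row.names = FALSE)
  utils::write.csv(study$windows, file.path(dir, "windows.csv"),
                   row.names = FALSE)
  invisible(dir)
}
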