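# End-to-end pipeline orchestration from a single YAML configuration:
# preprocess -> generate candidates -> build network -> iterate
# assignment -> evaluate -> export.

.config_defaults <- function() {
  list(tolerance_ppm = 2, align_ppm = 5, snr_min = 10, blank_ratio = 3,
       rsd_max = 30, cutoff = 3, adducts = names(ADDUCT_MASS),
       weights = list(degree = 0.5, mz = 0.3, iso = 0.2),
       max_rounds = 10, rescore_ambiguous = TRUE, normalize = TRUE,
       hc_ratio = c(0.4, 5.1), mass_range = c(50, 800), seed = 1)
}

.config_error <- function(...) {
  stop(structure(class = c("formnet_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

.input_error <- function(...) {
  stop(structure(class = c("formnet_input_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML file; any omitted key falls back to the
#' documented default. Validation fails fast naming the offending field.
#'
#' @param path YAML file path, or a named list to validate directly.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) .input_error("config file not found: ", path)
    yaml::read_yaml(path)
  }
  full <- utils::modifyList(.config_defaults(), cfg)
  for (f in c("tolerance_ppm", "align_ppm", "snr_min"))
    if (!is.numeric(full[[f]]) || full[[f]] <= 0)
      .config_error("config field '", f, "' must be > 0")
  if (full$cutoff < 1) .config_error("config field 'cutoff' must be >= 1")
  w <- full$weights
  if (any(unlist(w[c("degree", "mz", "iso")]) < 0))
    .config_error("config field 'weights' must be non-negative")
  if (full$rsd_max <= 0) .config_error("config field 'rsd_max' must be > 0")
  full
}

#' Run the full assignment pipeline from a configuration
#'
#' Reads per-sample peak lists and a manifest, preprocesses them into a
#' monoisotopic feature table, assigns formulas against the seed reaction
#' network, optionally evaluates against a truth table, and writes all
#' artifacts (feature table, assignment CSV, per-round JSON, GraphML
#' network, provenance record) into `out_dir`. Outputs are deterministic
#' for a fixed configuration.
#'
#' @param config Path to a YAML config or a named list. Recognized path
#'   keys: `manifest` (peak-list manifest CSV), `seeds` (seed formula
#'   list), `reactions` (reaction table CSV, optional), `windows`
#'   (window CSV with columns low,high; optional), `is_mz` (CSV of IS
#'   m/z values or numeric vector; optional), `truth` (truth CSV,
#'   optional), `out_dir`.
#' @return Invisibly, a list with the feature table, the
#'   `formula_assignment` and (if truth was supplied) the evaluation
#'   report.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  for (f in c("manifest", "seeds", "out_dir"))
    if (is.null(cfg[[f]])) .config_error("config field '", f, "' is required")
  for (f in c("manifest", "seeds", "reactions", "truth", "windows"))
    if (!is.null(cfg[[f]]) && is.character(cfg[[f]]) && !file.exists(cfg[[f]]))
      .input_error("input file for '", f, "' not found: ", cfg[[f]])

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_counts <- list()
  note <- function(stage, n) {
    log_counts[[stage]] <<- n
    message(sprintf("[formnet] %-22s %d", stage, n))
  }

  manifest <- read_manifest(cfg$manifest)
  windows <- if (!is.null(cfg$windows)) {
    w <- utils::read.csv(cfg$windows)
    window_scheme(w$low, w$high)
  } else default_window_scheme()
  scans <- lapply(manifest$file, function(f) {
    p <- read_peaks(f)
    if (is.null(p$window)) list(p)
    else lapply(seq_len(nrow(windows)), function(w)
      p[p$window == w, c("mz", "intensity", "snr"), drop = FALSE])
  })
  names(scans) <- manifest$sample
  roles <- stats::setNames(manifest$role, manifest$sample)

  merged <- lapply(scans, function(sc) {
    sch <- if (length(sc) == nrow(windows)) windows
           else window_scheme(min(windows$low), max(windows$high))
    filter_noise(stitch_windows(sc, sch), cfg$snr_min)
  })
  note("peaks after S/N", sum(vapply(merged, nrow, integer(1))))
  ft <- align_peaks(merged, tol_ppm = cfg$align_ppm, roles = roles)
  note("aligned features", n_features(ft))
  if (isTRUE(cfg$normalize) && !is.null(cfg$is_mz)) {
    is_mz <- if (is.character(cfg$is_mz)) utils::read.csv(cfg$is_mz)$mz
             else cfg$is_mz
    ft <- normalize_by_is(ft, is_mz)
  }
  if (any(roles == "blank")) {
    ft <- blank_reduction(ft, ratio_min = cfg$blank_ratio)
    note("after blank reduction", n_features(ft))
  }
  if (sum(roles == "qc") >= 2L) {
    ft <- rsd_qc_filter(ft, rsd_max = cfg$rsd_max)
    note("after QC RSD filter", n_features(ft))
  }
  ft <- flag_isotopologues(ft, tol_ppm = cfg$tolerance_ppm)
  note("monoisotopic features", sum(ft$monoisotopic))
  write_feature_table(ft, file.path(cfg$out_dir, "features.csv"))

  rules <- element_rules(hc_ratio = cfg$hc_ratio,
                         mass_range = cfg$mass_range)
  seeds <- read_seed_list(cfg$seeds)
  reactions <- if (!is.null(cfg$reactions)) read_reaction_table(cfg$reactions)
               else default_reactions()
  fit <- assign_formulas(features_for_assignment(ft), seeds = seeds,
                         reactions = reactions, rules = rules,
                         adducts = cfg$adducts,
                         tol_ppm = cfg$tolerance_ppm, cutoff = cfg$cutoff,
                         weights = score_weights(cfg$weights$degree,
                                                 cfg$weights$mz,
                                                 cfg$weights$iso),
                         max_rounds = cfg$max_rounds,
                         rescore_ambiguous = cfg$rescore_ambiguous)
  note("unique assignments", sum(fit$assignments$status == "unique"))
  write_assignment(fit, file.path(cfg$out_dir, "assignments.csv"))
  jsonlite::write_json(fit$rounds, file.path(cfg$out_dir, "rounds.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  export_network(fit$network, file.path(cfg$out_dir, "network.graphml"))

  report <- NULL
  if (!is.null(cfg$truth)) {
    truth <- utils::read.csv(cfg$truth, stringsAsFactors = FALSE)
    report <- coverage_accuracy(fit, truth, tol_ppm = cfg$tolerance_ppm)
    jsonlite::write_json(
      list(coverage = report$coverage, accuracy = report$accuracy,
           n_truth = report$n_truth, n_unique = report$n_unique,
           n_correct = report$n_correct),
      file.path(cfg$out_dir, "evaluation.json"), auto_unbox = TRUE,
      digits = NA)
  }

  cfg_file <- tempfile(fileext = ".rds")
  saveRDS(cfg[order(names(cfg))], cfg_file)
  prov <- list(package = "formnet",
               version = as.character(utils::packageVersion("formnet")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               config_md5 = unname(tools::md5sum(cfg_file)),
               seed = cfg$seed,
               timestamp = format(Sys.time(), tz = "UTC"),
               filter_log = log_counts)
  unlink(cfg_file)
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(list(features = ft, fit = fit, evaluation = report,
                 config = cfg))
}
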