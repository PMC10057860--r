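# Iterative multi-round formula assignment.
#
# Each round: connect every pending feature's candidates to the current
# network, apply the degree cut-off, score the survivors, and assign a
# feature when a strict top-scoring candidate exists. Newly assigned
# formulas join the network as nodes before the next round, so features
# whose candidates only neighbor other experimental metabolites become
# assignable later. Earlier assignments are never revoked, which makes the
# uniquely assigned set non-decreasing and guarantees termination.

.features_df <- function(features) {
  if (inherits(features, "feature_table")) features <- features_for_assignment(features)
  stopifnot(is.data.frame(features), "mz" %in% names(features))
  if (is.null(features$feature_id)) features$feature_id <- seq_len(nrow(features))
  if (is.null(features$m1_mz)) features$m1_mz <- NA_real_
  if (is.null(features$m1_ratio)) features$m1_ratio <- NA_real_
  features
}

#' One assignment round
#'
#' Connects each feature's candidates to the network, applies the degree
#' cut-off, scores survivors and classifies every feature as `unique`
#' (strict top score), `ambiguous` (tied top score) or `unassigned` (no
#' candidate above the cut-off).
#'
#' @param features Data.frame with columns `feature_id`, `mz` and
#'   optionally `m1_mz`, `m1_ratio` (experimental M+1 peak m/z and
#'   intensity ratio), or a feature table from [align_peaks()].
#' @param cand_sets Named list (by feature id) of candidate sets from
#'   [generate_candidates()].
#' @param net A `reaction_network`.
#' @param cutoff Degree cut-off (default 3).
#' @param weights [score_weights()].
#' @param tol_ppm Mass tolerance (ppm) used in the mass-accuracy and
#'   isotope scores.
#' @param tol_int Relative-intensity tolerance (fraction) of the isotope
#'   score.
#' @param cutoff_mode `">="` (default) or `">"`.
#' @return Data.frame with one row per feature: `feature_id`, `mz`,
#'   `status`, `adduct`, `formula`, `mz_theo`, `ppm_error`, `degree`,
#'   `identity`, `s_degree`, `s_mz`, `s_iso`, `score`, `n_candidates`,
#'   `n_connected`, `n_top`.
#' @export
assign_round <- function(features, cand_sets, net, cutoff = 3L,
                         weights = score_weights(), tol_ppm = 2,
                         tol_int = 5, cutoff_mode = ">=") {
  features <- .features_df(features)
  empty <- data.frame(status = "unassigned", adduct = NA_character_,
                      formula = NA_character_, mz_theo = NA_real_,
                      ppm_error = NA_real_, degree = NA_integer_,
                      identity = NA, s_degree = NA_real_, s_mz = NA_real_,
                      s_iso = NA_real_, score = NA_real_)
  rows <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    fid <- as.character(features$feature_id[i])
    cands <- cand_sets[[fid]]
    res <- empty
    res$n_candidates <- if (is.null(cands)) 0L else nrow(cands)
    res$n_connected <- 0L
    res$n_top <- 0L
    if (!is.null(cands) && nrow(cands) > 0L) {
      conn <- connect_candidates(net, cands)
      conn <- conn[conn$degree > 0L, , drop = FALSE]
      res$n_connected <- nrow(conn)
      surv <- degree_filter(conn, cutoff = cutoff, mode = cutoff_mode)
      if (nrow(surv) > 0L) {
        fm <- .as_counts(as.matrix(surv[, ELEMENTS]))
        m1 <- .m1_shell(fm)
        s_deg <- score_degree(surv$degree)
        s_m <- score_mz(features$mz[i], surv$mz_theo, tol_ppm)
        if (!is.na(features$m1_mz[i]) && !is.na(features$m1_ratio[i])) {
          s_i <- .score_iso_m1(features$m1_mz[i] - features$mz[i],
                               features$m1_ratio[i],
                               m1$offset, m1$rel_intensity,
                               mz_ref = features$m1_mz[i],
                               tol_ppm = tol_ppm, tol_int = tol_int)
        } else {
          s_i <- rep(0, nrow(surv))
        }
        total <- total_score(s_deg, s_m, s_i, weights)
        top <- max(total)
        n_top <- sum(total >= top - 1e-12)
        b <- which.max(total)
        res <- data.frame(
          status = if (n_top == 1L) "unique" else "ambiguous",
          adduct = surv$adduct[b], formula = surv$formula[b],
          mz_theo = surv$mz_theo[b], ppm_error = surv$ppm_error[b],
          degree = surv$degree[b], identity = surv$identity[b],
          s_degree = s_deg[b], s_mz = s_m[b], s_iso = s_i[b],
          score = total[b], n_candidates = nrow(cands),
          n_connected = nrow(conn), n_top = n_top)
        if (n_top > 1L) {
          # a tied top score defers the feature to a later round rather
          # than picking arbitrarily
          res$adduct <- NA_character_; res$formula <- NA_character_
          res$mz_theo <- NA_real_; res$ppm_error <- NA_real_
        }
      }
    }
    rows[[i]] <- res
  }
  cbind(features[, c("feature_id", "mz")], do.call(rbind, rows))
}

#' Iterative network-based formula assignment
#'
#' The main entry point: generates candidates for every feature (unless
#' supplied), builds the seed network, and runs assignment rounds until a
#' round adds no new unique assignment or `max_rounds` is reached. After
#' each round the newly assigned formulas are added to the network, and
#' unassigned (and, by default, ambiguous) features are re-evaluated
#' against the enlarged network. Assignments from earlier rounds are never
#' revoked.
#'
#' @inheritParams assign_round
#' @param seeds Seed formulas (character vector / count matrix) or a
#'   prebuilt `reaction_network`.
#' @param reactions Reaction table used when `seeds` is not already a
#'   network.
#' @param rules [element_rules()] for candidate generation and seed
#'   filtering.
#' @param adducts Adduct labels considered for each feature.
#' @param tol_ppm Mass tolerance in ppm for candidate generation and
#'   scoring (default 2).
#' @param max_rounds Maximum number of rounds (default 10).
#' @param rescore_ambiguous Re-evaluate ambiguous features in later rounds
#'   (default `TRUE`); unassigned features are always re-evaluated.
#' @param candidates Optional precomputed named list of candidate sets.
#' @param verbose Print per-round progress.
#' @return An object of class `formula_assignment`: a list with
#'   `assignments` (per-feature data.frame including `round`), `rounds`
#'   (per-round summary), `network` (final augmented network), `params`.
#' @export
#' @examples
#' feats <- data.frame(feature_id = 1, mz = ion_mz("C6H13O9P", "[M+H]+"))
#' fit <- assign_formulas(feats, seeds = c("C6H12O6", "C6H14O6"),
#'                        cutoff = 1, max_rounds = 2)
#' summary(fit)
assign_formulas <- function(features, seeds, reactions = default_reactions(),
                            rules = element_rules(),
                            adducts = names(ADDUCT_MASS), tol_ppm = 2,
                            cutoff = 3L, weights = score_weights(),
                            tol_int = 5, max_rounds = 10L,
                            rescore_ambiguous = TRUE, cutoff_mode = ">=",
                            candidates = NULL, verbose = FALSE) {
  stopifnot(max_rounds >= 1L)
  features <- .features_df(features)
  net <- if (inherits(seeds, "reaction_network")) seeds
         else build_network(seeds, reactions, rules)
  if (is.null(candidates)) {
    candidates <- lapply(seq_len(nrow(features)), function(i)
      generate_candidates(features$mz[i], adducts, tol_ppm, rules))
    names(candidates) <- as.character(features$feature_id)
  }
  assigned <- NULL
  pending <- features
  rounds <- list()
  for (k in seq_len(max_rounds)) {
    res <- assign_round(pending, candidates, net, cutoff = cutoff,
                        weights = weights, tol_ppm = tol_ppm,
                        tol_int = tol_int, cutoff_mode = cutoff_mode)
    res$round <- ifelse(res$status == "unique", k, NA_integer_)
    new_unique <- res[res$status == "unique", , drop = FALSE]
    rounds[[k]] <- data.frame(
      round = k, n_evaluated = nrow(res), n_new_unique = nrow(new_unique),
      n_ambiguous = sum(res$status == "ambiguous"),
      n_unassigned = sum(res$status == "unassigned"),
      n_nodes = nrow(net$nodes), n_edges = nrow(net$edges))
    if (verbose)
      message("round ", k, ": ", nrow(new_unique), " new unique, ",
              sum(res$status == "ambiguous"), " ambiguous, ",
              sum(res$status == "unassigned"), " unassigned")
    assigned <- rbind(assigned, new_unique)
    leftover <- res[res$status != "unique", , drop = FALSE]
    if (nrow(new_unique) == 0L || nrow(leftover) == 0L || k == max_rounds) {
      assigned <- rbind(assigned, leftover)
      break
    }
    net <- add_assigned_nodes(net, new_unique$formula, round = k)
    keep <- if (rescore_ambiguous) leftover$feature_id else
      leftover$feature_id[leftover$status == "unassigned"]
    if (!rescore_ambiguous)
      assigned <- rbind(assigned,
                        leftover[leftover$status == "ambiguous", , drop = FALSE])
    pending <- features[features$feature_id %in% keep, , drop = FALSE]
    if (nrow(pending) == 0L) break
  }
  assignments <- assigned[order(match(assigned$feature_id,
                                      features$feature_id)), , drop = FALSE]
  rownames(assignments) <- NULL
  structure(list(assignments = assignments,
                 rounds = do.call(rbind, rounds), network = net,
                 params = list(tol_ppm = tol_ppm, cutoff = cutoff,
                               weights = weights, tol_int = tol_int,
                               adducts = adducts, max_rounds = max_rounds,
                               rescore_ambiguous = rescore_ambiguous,
                               cutoff_mode = cutoff_mode)),
            class = "formula_assignment")
}

#' @export
print.formula_assignment <- function(x, ...) {
  a <- x$assignments
  cat("Formula assignment over ", nrow(a), " features (",
      nrow(x$rounds), " round(s))\n", sep = "")
  cat("  unique:    ", sum(a$status == "unique"), "\n")
  cat("  ambiguous: ", sum(a$status == "ambiguous"), "\n")
  cat("  unassigned:", sum(a$status == "unassigned"), "\n")
  invisible(x)
}

#' @export
summary.formula_assignment <- function(object, ...) {
  a <- object$assignments
  out <- list(n_features = nrow(a),
              n_unique = sum(a$status == "unique"),
              n_ambiguous = sum(a$status == "ambiguous"),
              n_unassigned = sum(a$status == "unassigned"),
              by_round = object$rounds,
              median_abs_ppm = stats::median(abs(a$ppm_error), na.rm = TRUE))
  class(out) <- "summary.formula_assignment"
  out
}

#' @export
print.summary.formula_assignment <- function(x, ...) {
  cat("Features:", x$n_features,
      "| unique:", x$n_unique,
      "| ambiguous:", x$n_ambiguous,
      "| unassigned:", x$n_unassigned, "\n")
  if (!is.na(x$median_abs_ppm))
    cat("Median |ppm error| of assignments:",
        signif(x$median_abs_ppm, 3), "\n")
  cat("\nPer-round summary:\n")
  print(x$by_round, row.names = FALSE)
  invisible(x)
}

#' Plot cumulative unique assignments per round
#'
#' @param x A `formula_assignment`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.formula_assignment <- function(x, ...) {
  cum <- cumsum(x$rounds$n_new_unique)
  graphics::barplot(cum, names.arg = x$rounds$round,
                    xlab = "assignment round",
                    ylab = "cumulative unique assignments", ...)
  invisible(x)
}

#' Write an assignment table to CSV
#'
#' @param x A `formula_assignment`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(x, path) {
  utils::write.csv(x$assignments, path, row.names = FALSE)
  invisible(path)
}
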