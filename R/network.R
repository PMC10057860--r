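# Mass-difference reaction networks: nodes are molecular formulas, an
# undirected edge links two formulas whose elemental difference (up to
# overall sign) equals one of the predefined biochemical transformations.

#' Read a reaction table
#'
#' A reaction table lists named formula differences ("edge species"), one
#' per row of a CSV with columns `name` and `difference` (Hill-notation
#' formula of the absolute difference). Matching is on the unsigned
#' difference, so each transformation is listed once.
#'
#' @param path Path to the CSV file.
#' @return A data.frame of class `reaction_table` with columns `name`,
#'   `difference` and the element counts; the count matrix is available via
#'   [reaction_diffs()].
#' @export
read_reaction_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "difference") %in% names(df)))
    stop("reaction table needs columns 'name' and 'difference': ", path)
  fm <- parse_formula(df$difference)
  if (any(rowSums(fm) == 0L)) stop("reaction differences must be non-zero")
  if (anyDuplicated(.formula_key(fm)))
    stop("duplicate reaction differences in ", path)
  out <- data.frame(name = df$name, difference = format_formula(fm), fm)
  class(out) <- c("reaction_table", "data.frame")
  out
}

#' Default reaction table
#'
#' The table of common biochemical formula differences shipped with the
#' package (hydrogenation, oxidation, (de)hydration, methylation,
#' acetylation, carboxylation, phosphorylation, sulfation, glycosylation,
#' amino-acid residue transfers, ...). It is an ordinary CSV under
#' `system.file("extdata", "reactions.csv", package = "formnet")` and can be
#' copied and edited; every network operation is parameterized by the table
#' it is given.
#'
#' @return A `reaction_table` data.frame.
#' @export
default_reactions <- function() {
  read_reaction_table(system.file("extdata", "reactions.csv",
                                  package = "formnet", mustWork = TRUE))
}

#' Reaction difference count matrix
#'
#' @param reactions A `reaction_table`.
#' @return Integer matrix of element counts, one row per reaction.
#' @export
reaction_diffs <- function(reactions) {
  .as_counts(as.matrix(reactions[, ELEMENTS]))
}

# Edges among `nodes` (count matrix): for each reaction difference d, node
# pairs (i, j) with counts[j] - counts[i] = d. Scanning the +d direction
# only finds each unordered pair exactly once.
.find_edges <- function(nodes, keys, reactions) {
  diffs <- reaction_diffs(reactions)
  pieces <- vector("list", nrow(diffs))
  for (r in seq_len(nrow(diffs))) {
    tgt <- sweep(nodes, 2L, diffs[r, ], "+")
    j <- match(.formula_key(tgt), keys)
    hit <- which(!is.na(j))
    if (length(hit))
      pieces[[r]] <- data.frame(from = hit, to = j[hit],
                                reaction = reactions$name[r])
  }
  edges <- do.call(rbind, pieces)
  if (is.null(edges))
    edges <- data.frame(from = integer(), to = integer(),
                        reaction = character())
  # self-loops cannot occur (differences are non-zero); keep one edge per
  # node pair even if several reactions share a difference direction
  edges <- edges[!duplicated(paste(pmin(edges$from, edges$to),
                                   pmax(edges$from, edges$to))), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

.network_from <- function(nodes, origin, round, reactions) {
  keys <- .formula_key(nodes)
  edges <- .find_edges(nodes, keys, reactions)
  degree <- tabulate(c(edges$from, edges$to), nbins = nrow(nodes))
  structure(list(nodes = nodes, formula = format_formula(nodes), keys = keys,
                 origin = origin, round = round, edges = edges,
                 degree = degree, reactions = reactions),
            class = "reaction_network")
}

#' Build the initial seed reaction network
#'
#' Seeds are deduplicated, restricted to the allowed elements and the
#' configured neutral mass range, and connected pairwise: an undirected
#' edge is placed between two seeds whenever their formula difference (up
#' to overall sign) equals one of the reaction-table differences.
#'
#' @param seeds Character vector of seed formulas (or a count matrix).
#' @param reactions A `reaction_table` (default [default_reactions()]).
#' @param rules An [element_rules()] object; only its element set and mass
#'   range are applied to seeds (database formulas are trusted otherwise).
#' @return An object of class `reaction_network` with components `nodes`
#'   (count matrix), `formula`, `origin` (`"seed"` or `"assigned-round-k"`),
#'   `round`, `edges` (data.frame `from`, `to`, `reaction`), `degree` and
#'   `reactions`.
#' @export
#' @examples
#' net <- build_network(c("C6H12O6", "C6H13O9P"))
#' network_stats(net)
build_network <- function(seeds, reactions = default_reactions(),
                          rules = element_rules()) {
  nodes <- .as_counts(seeds)
  if (nrow(nodes) == 0L) stop("seed list is empty")
  nodes <- nodes[!duplicated(.formula_key(nodes)), , drop = FALSE]
  seed_rules <- element_rules(elements = rules$elements,
                              hc_ratio = c(0, Inf),
                              mass_range = rules$mass_range)
  nodes <- nodes[check_constraints(nodes, seed_rules), , drop = FALSE]
  if (nrow(nodes) == 0L)
    stop("no seed formulas remain after element/mass-range filtering")
  .network_from(nodes, origin = rep("seed", nrow(nodes)),
                round = rep(0L, nrow(nodes)), reactions = reactions)
}

#' Add assigned formulas to a network
#'
#' Newly assigned unique formulas become nodes labelled with the assignment
#' round, and the edge set is recomputed over the enlarged node set (the
#' result is identical to incremental edge insertion because edges depend
#' only on the node set).
#'
#' @param net A `reaction_network`.
#' @param formulas Character vector or count matrix of new node formulas;
#'   formulas already present are ignored.
#' @param round Integer round index recorded as the origin of the new nodes.
#' @return The enlarged `reaction_network`.
#' @export
add_assigned_nodes <- function(net, formulas, round) {
  fm <- .as_counts(formulas)
  fm <- fm[!duplicated(.formula_key(fm)), , drop = FALSE]
  fm <- fm[!.formula_key(fm) %in% net$keys, , drop = FALSE]
  if (nrow(fm) == 0L) return(net)
  nodes <- rbind(net$nodes, fm)
  origin <- c(net$origin, rep(paste0("assigned-round-", round), nrow(fm)))
  rounds <- c(net$round, rep(as.integer(round), nrow(fm)))
  .network_from(nodes, origin, rounds, net$reactions)
}

#' Connect candidate formulas to a network
#'
#' For each candidate formula, the degree is the number of distinct network
#' nodes whose difference to the candidate matches a reaction. A candidate
#' identical to an existing node is flagged (`identity = TRUE`); its degree
#' is the node's own degree, which falls out of the same pairwise matching.
#' Candidate-candidate relations are deliberately not counted: evidence
#' accrues only from established network nodes.
#'
#' @param net A `reaction_network`.
#' @param cands A `candidate_set` data.frame (or any data.frame containing
#'   element-count columns), or a formula count matrix / character vector.
#' @param reactions Reaction table; defaults to the network's own.
#' @return The input candidates augmented with columns `degree` (integer)
#'   and `identity` (logical). Candidates with degree 0 are unconnected.
#' @export
connect_candidates <- function(net, cands, reactions = net$reactions) {
  if (is.data.frame(cands)) {
    fm <- .as_counts(as.matrix(cands[, ELEMENTS]))
    out <- cands
  } else {
    fm <- .as_counts(cands)
    out <- data.frame(formula = format_formula(fm), fm)
  }
  diffs <- reaction_diffs(reactions)
  n <- nrow(fm)
  neighbor <- vector("list", n)
  if (n > 0L) {
    for (r in seq_len(nrow(diffs))) {
      for (sgn in c(1L, -1L)) {
        tgt <- sweep(fm, 2L, sgn * diffs[r, ], "+")
        j <- match(.formula_key(tgt), net$keys)
        hit <- which(!is.na(j))
        for (i in hit) neighbor[[i]] <- c(neighbor[[i]], j[i])
      }
    }
  }
  out$degree <- vapply(neighbor, function(v) length(unique(v)), integer(1))
  out$identity <- .formula_key(fm) %in% net$keys
  attr(out, "neighbors") <- lapply(neighbor, unique)
  out
}

#' Filter connected candidates by network degree
#'
#' Retains candidates whose degree meets the cut-off. The default semantics
#' is `degree >= cutoff`; `mode = ">"` switches to a strict cut-off.
#'
#' @param connected Output of [connect_candidates()].
#' @param cutoff Integer degree cut-off (>= 1).
#' @param mode `">="` (default) or `">"`.
#' @return The retained rows.
#' @export
degree_filter <- function(connected, cutoff = 3L, mode = c(">=", ">")) {
  stopifnot(cutoff >= 1L)
  mode <- match.arg(mode)
  keep <- if (mode == ">=") connected$degree >= cutoff else connected$degree > cutoff
  connected[keep, , drop = FALSE]
}

#' Descriptive statistics of a reaction network
#'
#' @param net A `reaction_network`.
#' @return A list with `n_nodes`, `n_edges`, `mean_degree` (2E/V, 0 for an
#'   empty network), `degree_hist` (named table) and `frac_below` — a
#'   function giving the fraction of nodes with degree below a threshold.
#' @export
network_stats <- function(net) {
  v <- nrow(net$nodes); e <- nrow(net$edges)
  list(n_nodes = v, n_edges = e,
       mean_degree = if (v > 0) 2 * e / v else 0,
       degree_hist = table(net$degree),
       frac_below = function(k) if (v > 0) mean(net$degree < k) else 0)
}

#' @export
print.reaction_network <- function(x, ...) {
  s <- network_stats(x)
  cat("Reaction network: ", s$n_nodes, " nodes, ", s$n_edges,
      " edges (mean degree ", round(s$mean_degree, 2), ")\n", sep = "")
  cat("  reactions:", nrow(x$reactions), " edge species\n")
  n_seed <- sum(x$origin == "seed")
  if (n_seed < s$n_nodes)
    cat("  origin: ", n_seed, " seed + ", s$n_nodes - n_seed,
        " assigned\n", sep = "")
  invisible(x)
}

#' Convert a reaction network to an igraph object
#'
#' @param net A `reaction_network`.
#' @return An undirected `igraph` graph with vertex attributes `formula`,
#'   `origin`, `round` and edge attribute `reaction`.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = nrow(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$formula)
  g <- igraph::set_vertex_attr(g, "formula", value = net$formula)
  g <- igraph::set_vertex_attr(g, "origin", value = net$origin)
  g <- igraph::set_vertex_attr(g, "round", value = net$round)
  if (nrow(net$edges) > 0L) {
    g <- igraph::add_edges(g, rbind(net$edges$from, net$edges$to))
    g <- igraph::set_edge_attr(g, "reaction", value = net$edges$reaction)
  }
  g
}

#' Export a network for Cytoscape
#'
#' Writes GraphML (or SIF) so the network can be inspected in Cytoscape or
#' any graph tool.
#'
#' @param net A `reaction_network`.
#' @param path Output file path.
#' @param format `"graphml"` (default) or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    lines <- sprintf("%s\t%s\t%s", net$formula[net$edges$from],
                     gsub("[\t ]+", "_", net$edges$reaction),
                     net$formula[net$edges$to])
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a seed formula list
#'
#' Accepts either a plain text file with one formula per line (blank lines
#' and `#` comments ignored) or a CSV whose `formula` column (or second
#' column) holds the formulas.
#'
#' @param path Path to the file.
#' @return Character vector of formulas.
#' @export
read_seed_list <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    col <- if ("formula" %in% names(df)) "formula" else names(df)[min(2L, ncol(df))]
    out <- df[[col]]
  } else {
    out <- readLines(path)
  }
  out <- trimws(out)
  out[nzchar(out) & !startsWith(out, "#")]
}
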