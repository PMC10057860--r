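# Reaction-network construction, candidate connection, degree filtering.

test_that("a single matching pair yields one edge with both degrees 1", {
  net <- build_network(c("C6H12O6", "C6H13O9P"))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$degree, c(1L, 1L))
  expect_equal(net$edges$reaction, "phosphorylation")
  s <- network_stats(net)
  expect_equal(s$mean_degree, 1)
})

test_that("no edge appears without a matching reaction difference", {
  net <- build_network(c("C6H12O6", "C10H16N5O13P3"))
  expect_equal(nrow(net$edges), 0L)
  expect_equal(network_stats(net)$mean_degree, 0)
})

test_that("edge set equals the O(n^2) brute-force oracle on random seeds", {
  u <- make_seed_universe(200, connectivity = 4, seed = 41)
  net <- build_network(u)
  expect_equal(net$formula, as.character(u)) # order preserved, no filtering
  oracle <- oracle_edges(net$formula, reaction_diffs(net$reactions))
  expect_equal(net_edge_keys(net), oracle)
  # degree histogram consistent with an independent recount
  recount <- tabulate(c(net$edges$from, net$edges$to),
                      nbins = nrow(net$nodes))
  expect_equal(net$degree, recount)
  expect_equal(sum(net$degree), 2L * nrow(net$edges))
})

test_that("edge construction is invariant to seed order", {
  u <- make_seed_universe(80, connectivity = 4, seed = 42)
  net1 <- build_network(u)
  set.seed(42)
  perm <- sample(seq_along(u))
  net2 <- build_network(u[perm])
  pairs1 <- sort(paste(pmin(net1$formula[net1$edges$from],
                            net1$formula[net1$edges$to]),
                       pmax(net1$formula[net1$edges$from],
                            net1$formula[net1$edges$to])))
  pairs2 <- sort(paste(pmin(net2$formula[net2$edges$from],
                            net2$formula[net2$edges$to]),
                       pmax(net2$formula[net2$edges$from],
                            net2$formula[net2$edges$to])))
  expect_equal(pairs1, pairs2)
})

test_that("candidate connection degrees match brute-force pairwise matching", {
  u <- make_seed_universe(500, connectivity = 4, seed = 43)
  net <- build_network(u)
  set.seed(44)
  # candidates: a mix of universe members, their neighbors and randoms
  cands <- unique(c(sample(u, 40),
                    make_decoys(60, u, seed = 45)))
  conn <- connect_candidates(net, parse_formula(cands))
  diffs <- reaction_diffs(net$reactions)
  rkeys <- c(apply(diffs, 1L, paste, collapse = " "),
             apply(-diffs, 1L, paste, collapse = " "))
  cfm <- parse_formula(cands)
  nfm <- net$nodes
  oracle_deg <- integer(length(cands))
  for (i in seq_along(cands)) {
    d <- sweep(nfm, 2L, cfm[i, ], "-")
    keys <- apply(d, 1L, paste, collapse = " ")
    oracle_deg[i] <- sum(keys %in% rkeys)
  }
  expect_equal(conn$degree, oracle_deg)
  expect_equal(conn$identity, cands %in% u)
})

test_that("a candidate one reaction from a node connects; others do not", {
  net <- build_network(c("C6H13O9P", "C3H7NO2"))
  conn <- connect_candidates(net, parse_formula(c("C6H12O6", "C20H30N2O4")))
  expect_gte(conn$degree[1], 1L)
  expect_equal(conn$degree[2], 0L)
})

test_that("degree filter retains by cut-off with >= semantics", {
  con <- data.frame(formula = c("a", "b", "c"), degree = c(1L, 2L, 3L),
                    identity = FALSE)
  expect_equal(degree_filter(con, 2)$degree, c(2L, 3L))
  expect_equal(nrow(degree_filter(con, 1)), 3L)
  expect_equal(nrow(degree_filter(con, 5)), 0L)
  expect_equal(degree_filter(con, 2, mode = ">")$degree, 3L)
})

test_that("adding nodes never decreases existing degrees", {
  u <- make_seed_universe(60, connectivity = 4, seed = 46)
  net <- build_network(u)
  grown <- add_assigned_nodes(net, make_decoys(30, u, seed = 47), round = 1)
  idx <- match(net$formula, grown$formula)
  expect_true(all(grown$degree[idx] >= net$degree))
  expect_true(all(grown$origin[idx] == "seed"))
  # re-adding existing formulas is a no-op
  expect_equal(nrow(add_assigned_nodes(net, u[1:5], 1)$nodes),
               nrow(net$nodes))
})

test_that("a reaction-closed chain has mean degree near the chain bound", {
  # successive methylations: each member one reaction from the next
  chain <- vapply(0:19, function(k)
    format_formula(formnet:::.as_counts(c(C = 6 + k, H = 12 + 2 * k, O = 6))),
    character(1))
  net <- build_network(chain)
  n <- length(chain)
  expect_gte(network_stats(net)$mean_degree, 2 * (n - 1) / n)
})

test_that("network stats fractions are consistent with the histogram", {
  u <- make_seed_universe(150, connectivity = 4, seed = 48)
  net <- build_network(u)
  s <- network_stats(net)
  h <- s$degree_hist
  frac <- sum(h[as.integer(names(h)) < 3]) / sum(h)
  expect_equal(s$frac_below(3), frac)
})

test_that("seed and reaction tables round-trip through their file formats", {
  tmp <- tempfile(fileext = ".txt")
  writeLines(c("# seeds", "C6H12O6", "", "C3H7NO2"), tmp)
  expect_equal(read_seed_list(tmp), c("C6H12O6", "C3H7NO2"))
  tmp2 <- tempfile(fileext = ".csv")
  writeLines(c("id,formula", "1,C6H12O6", "2,C3H7NO2"), tmp2)
  expect_equal(read_seed_list(tmp2), c("C6H12O6", "C3H7NO2"))
  rt <- default_reactions()
  expect_true(all(c("name", "difference") %in% names(rt)))
  expect_false(any(duplicated(formnet:::.formula_key(reaction_diffs(rt)))))
  bad <- tempfile(fileext = ".csv")
  writeLines(c("name,difference", "a,CH2", "b,CH2"), bad)
  expect_error(read_reaction_table(bad), "duplicate")
})

test_that("networks export to GraphML and SIF", {
  net <- build_network(c("C6H12O6", "C6H13O9P", "C7H15O9P"))
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), nrow(net$edges))
  f1 <- tempfile(fileext = ".graphml"); f2 <- tempfile(fileext = ".sif")
  export_network(net, f1)
  export_network(net, f2, format = "sif")
  expect_true(file.size(f1) > 0 && file.size(f2) > 0)
  expect_match(readLines(f2)[1], "\t")
})
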