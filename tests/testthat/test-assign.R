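# Multi-round assignment mechanics.

# chain fixture: seed A -- B -- C, where B is one phosphorylation from the
# seed and C one methylation from B; C has no direct link to A, so it can
# only be assigned after B has joined the network.
chain_fixture <- function() {
  rt_file <- tempfile(fileext = ".csv")
  writeLines(c("name,difference",
               "phosphorylation,HPO3",
               "methylation,CH2"), rt_file)
  list(seeds = "C6H12O6",
       reactions = read_reaction_table(rt_file),
       features = data.frame(
         feature_id = c("B", "C"),
         mz = ion_mz(c("C6H13O9P", "C7H15O9P"), "[M+H]+")))
}

test_that("the seed--B--C chain resolves B in round 1 and C in round 2", {
  fx <- chain_fixture()
  fit <- assign_formulas(fx$features, seeds = fx$seeds,
                         reactions = fx$reactions, adducts = "[M+H]+",
                         cutoff = 1, max_rounds = 5)
  a <- fit$assignments
  expect_equal(a$status, c("unique", "unique"))
  expect_equal(a$formula[a$feature_id == "B"], "C6H13O9P")
  expect_equal(a$round[a$feature_id == "B"], 1L)
  expect_equal(a$formula[a$feature_id == "C"], "C7H15O9P")
  expect_equal(a$round[a$feature_id == "C"], 2L)
  # cumulative unique set is non-decreasing and conserved
  expect_equal(fit$rounds$n_new_unique[1:2], c(1L, 1L))
  expect_equal(sum(fit$rounds$n_new_unique), sum(a$status == "unique"))
})

test_that("features with no network-connected candidate stay unassigned", {
  fx <- chain_fixture()
  # seed far from both features' candidate space
  fit <- assign_formulas(fx$features["2", , drop = FALSE], seeds = fx$seeds,
                         reactions = fx$reactions, adducts = "[M+H]+",
                         cutoff = 1, max_rounds = 5)
  expect_equal(fit$assignments$status, "unassigned")
  expect_equal(nrow(fit$rounds), 1L)
})

test_that("tied top scores defer a feature instead of picking arbitrarily", {
  # two seeds, each one methylation from a shared candidate mass window:
  # construct two candidates with identical degree and symmetric ppm error
  rt_file <- tempfile(fileext = ".csv")
  writeLines(c("name,difference", "methylation,CH2"), rt_file)
  rt <- read_reaction_table(rt_file)
  cands <- data.frame(
    adduct = "[M+H]+",
    formula = c("C6H12O6", "C7H14O6"),
    parse_formula(c("C6H12O6", "C7H14O6")),
    mz_theo = ion_mz(c("C6H12O6", "C7H14O6"), "[M+H]+"),
    ppm_error = c(0, 0))
  feats <- data.frame(feature_id = "X", mz = ion_mz("C6H12O6", "[M+H]+"))
  fit <- assign_formulas(feats, seeds = c("C5H10O6", "C8H16O6"),
                         reactions = rt, cutoff = 1,
                         candidates = list(X = cands),
                         weights = score_weights(0.5, 0, 0))
  expect_equal(fit$assignments$status, "ambiguous")
  expect_true(is.na(fit$assignments$formula))
  expect_equal(fit$assignments$n_top, 2L)
})

test_that("assignment is deterministic and candidate-order invariant", {
  st <- make_study(n_seeds = 300, n_truth = 30, n_noise = 50, seed = 61)
  ft <- process_study(st)
  feats <- features_for_assignment(ft)
  cands <- lapply(seq_len(nrow(feats)), function(i)
    generate_candidates(feats$mz[i]))
  names(cands) <- as.character(feats$feature_id)
  fit1 <- assign_formulas(feats, seeds = st$universe, candidates = cands)
  set.seed(62)
  perm_cands <- lapply(cands, function(cs) {
    out <- cs[sample(nrow(cs)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  fit2 <- assign_formulas(feats, seeds = st$universe,
                          candidates = perm_cands)
  expect_equal(fit1$assignments$formula, fit2$assignments$formula)
  expect_equal(fit1$assignments$status, fit2$assignments$status)
  expect_equal(fit1$assignments$round, fit2$assignments$round)
  fit3 <- assign_formulas(feats, seeds = st$universe, candidates = cands)
  expect_identical(fit1$assignments, fit3$assignments)
})

test_that("the loop terminates and uniques accumulate monotonically", {
  st <- make_study(n_seeds = 300, n_truth = 30, n_noise = 50, seed = 63)
  ft <- process_study(st)
  fit <- assign_formulas(features_for_assignment(ft), seeds = st$universe,
                         max_rounds = 25)
  expect_lte(nrow(fit$rounds), nrow(fit$assignments))
  expect_true(all(fit$rounds$n_new_unique >= 0))
  expect_equal(sum(fit$rounds$n_new_unique),
               sum(fit$assignments$status == "unique"))
  s <- summary(fit)
  expect_equal(s$n_unique + s$n_ambiguous + s$n_unassigned, s$n_features)
})

test_that("single-round output matches a step-by-step manual pipeline", {
  st <- make_study(n_seeds = 300, n_truth = 25, n_noise = 40, seed = 64)
  ft <- process_study(st)
  feats <- features_for_assignment(ft)[1:15, ]
  net <- build_network(st$universe)
  cands <- lapply(seq_len(nrow(feats)), function(i)
    generate_candidates(feats$mz[i]))
  names(cands) <- as.character(feats$feature_id)
  res <- assign_round(feats, cands, net, cutoff = 3)
  w <- score_weights()
  for (i in seq_len(nrow(feats))) {
    cs <- cands[[as.character(feats$feature_id[i])]]
    conn <- connect_candidates(net, cs)
    surv <- conn[conn$degree >= 3, , drop = FALSE]
    if (nrow(surv) == 0L) {
      expect_equal(res$status[i], "unassigned")
      next
    }
    sd_ <- surv$degree / max(surv$degree)
    sm_ <- abs(feats$mz[i] - surv$mz_theo) / feats$mz[i] * 1e6 / 2
    tot <- w$degree * sd_ - w$mz * sm_
    if (!is.na(feats$m1_mz[i])) {
      m1t <- formnet:::.m1_shell(as.matrix(surv[, c("C","H","N","O","P","S")]))
      smz1 <- pmax(0, 1 - abs((feats$m1_mz[i] - feats$mz[i]) - m1t$offset) /
                     feats$m1_mz[i] * 1e6 / 2)
      sint <- pmax(0, 1 - (abs(feats$m1_ratio[i] - m1t$rel_intensity) /
                             m1t$rel_intensity) / 5)
      tot <- tot + w$iso * (0.5 * smz1 + 0.5 * sint)
    }
    top <- which(tot >= max(tot) - 1e-12)
    if (length(top) == 1L) {
      expect_equal(res$status[i], "unique")
      expect_equal(res$formula[i], surv$formula[top])
    } else {
      expect_equal(res$status[i], "ambiguous")
    }
  }
})
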