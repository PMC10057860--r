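---
title: "Reaction-network formula assignment for direct-infusion HRMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-network formula assignment for direct-infusion HRMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formnet)
```

## The problem

Direct-infusion nano-electrospray HRMS (DI-nESI-HRMS) measures a serum
metabolome in well under a minute, but offers no chromatographic
separation: every ion must be annotated from its mass alone. At a 2 ppm
tolerance a single m/z value in the 300–600 Th range is compatible with
tens to hundreds of CHNOPS formulas, and a database lookup only ever
annotates compounds the database happens to contain. `formnet` implements
a database-independent middle road: *every* formula consistent with the
measured mass is enumerated, and biochemical plausibility — proximity to
known metabolism under a table of elemental reaction differences — is
used to filter and rank the candidates.

## The method

**Candidate enumeration.** For a feature at measured m/z and each adduct
in $\{[M+H]^+, [M+Na]^+, [M+K]^+\}$, the neutral target mass window is
$m/z\,(1 \pm \text{tol}) - m_{\text{adduct}} + m_e$; the electron mass
$m_e$ is subtracted from ion masses because a singly charged cation has
lost one electron — omitting it shifts ions by ~2.7 ppm at m/z 200,
larger than the tolerance itself. Every integer CHNOPS composition in the
window is enumerated exhaustively (nested loops over P, S, N, O, C with
mass-derived bounds, hydrogen solved last), then filtered by element
rules: H/C ratio in [0.4, 5.1] when carbon is present (the ratio is
undefined at C = 0, so carbon-free formulas skip the test), neutral mass
in [50, 800] Da, optional per-element count bounds and an optional RDBE
range (off by default — common practice is divided on it, and the method
does not depend on it).

**The seed network.** Known metabolite formulas (e.g. an HMDB export, or
the synthetic universe described below) become nodes; an undirected edge
connects two formulas whose componentwise difference, up to overall sign,
equals one of the tabulated reaction differences (hydration, methylation,
acetylation, phosphorylation, glycosylation, amino-acid residue
transfers, ...). The table shipped at
`system.file("extdata", "reactions.csv", package = "formnet")` lists 44
common biochemical transformations and is an ordinary CSV: swapping in a
custom table reparameterizes the whole method. Matching is unsigned
because a mass difference carries no reaction direction.

**Degree filtering.** A candidate's *degree* is the number of network
nodes one reaction away from it. Candidates below the degree cut-off
(default 3) are discarded; a candidate identical to a seed node keeps the
node's own degree and is flagged as an identity match. The cut-off
default follows the calibration that pairs a cut-off of 3 with seed
networks of mean degree ≈ 10 (denser networks support stricter cut-offs;
the cut-off is a run-time parameter, and `degree_filter()` exposes both
`>=` and `>` semantics since either convention appears in practice).

**Scoring.** Surviving candidates are ranked by

$$S = w_{\text{deg}} S_{\text{deg}} - w_{m/z} S_{m/z} + w_{\text{iso}} S_{\text{iso}}$$

with default weights (0.5, 0.3, 0.2). $S_{m/z}$ is the absolute ppm error
normalized by the tolerance (0 at an exact match, 1 at the boundary) and
enters as a penalty. $S_{\text{deg}}$ is the candidate's degree divided
by the maximum degree among that feature's candidates — the
normalization makes the term commensurate with the other [0, 1] scores;
it is per-feature because degree only has to order candidates of the same
feature. $S_{\text{iso}} = \tfrac12 S^{(1)}_{m/z} + \tfrac12 S_{\text{int}}$
compares the experimental M+1 isotopologue peak with the candidate's
predicted M+1 shell, with the m/z part normalized by the 2 ppm tolerance
and the intensity part by a 500% relative-intensity tolerance, each
floored at 0; when no experimental M+1 was detected the term is 0 for
every candidate, contributing no discrimination rather than a penalty.
Isotope patterns are shell-aggregated (M+1, M+2) rather than resolved
fine structure: the score compares one (m/z, intensity) pair per shell,
which aggregation provides exactly, and the M+1 shell has a closed form
(the sum over elements of count × abundance ratio) that the test suite
cross-checks against full polynomial expansion and brute-force
isotopologue enumeration.

**Iterative assignment.** A feature with a strict top-scoring candidate
is assigned; an exact score tie defers the feature rather than picking
arbitrarily. After each round, newly assigned formulas join the network
as nodes, degrees are recomputed, and unassigned features — plus, by
default, previously tied ones — are re-evaluated. Because assignments are
never revoked, the uniquely assigned set grows monotonically and the loop
terminates (at the latest after one round per feature; in practice 2–4
rounds). This is what lets metabolites with no *direct* seed neighbor be
assigned through intermediate experimental metabolites.

## Preprocessing

Per-window centroid scans are merged by spectral stitching: in the
overlap of two adjacent acquisition windows each peak is taken from
exactly one window, with the boundary at the overlap midpoint — a
deterministic, symmetric rule that also avoids peaks measured at window
edges where mass accuracy degrades. The default scheme is the nine
overlapping windows spanning m/z 65–609 used for serum. Noise filtering
keeps peaks with S/N strictly above 10 (a literal reading of the usual
"S/N > 10" criterion). Alignment across samples is greedy
single-linkage in ascending m/z against the cluster's running
intensity-weighted mean at 5 ppm — deterministic and standard for
direct-infusion data, which has no retention-time axis. Blank reduction
keeps features whose mean sample intensity is at least 3× the mean blank
intensity (3 is a configurable convention; features absent from blanks
always survive). Internal-standard normalization divides every feature by
its nearest-in-m/z IS; it runs *before* blank reduction because the ISs
are spiked into blanks as well, so the 3-fold rule would otherwise remove
the IS features before they could be located — the normalization ratio
itself is unaffected by the ordering. QC repeatability filtering keeps
features with RSD < 30% over the QC injections. Finally, a feature is
flagged non-monoisotopic when another feature one 13C–12C mass unit below
it (±2 ppm) makes it a plausible M+1 partner — the observed intensity
ratio must not exceed 1.5× the largest M+1 fraction any CHNOPS formula of
that mass could have (an all-carbon skeleton at 1.07% per carbon). The
nearest-IS mapping and the de-isotoping bound are stand-in conventions:
real studies know their IS panel and can supply an explicit mapping.

## The synthetic-study generator

`make_study()` produces everything the pipeline consumes, with known
ground truth and bit-reproducibility under a seed. Its defaults define
the study conditions the package is validated under:

* **Universe**: 2000 formulas grown to a target network mean degree of 10
  (`connectivity`), matching the density of curated endogenous-metabolite
  networks (a 5324-node endogenous network with 27,598 edges has mean
  degree 10.4), which is also the density regime that justifies the
  degree cut-off of 3. Growth mixes three proposals: 5% "orphan" random
  formulas with no tabulated reaction partner, single reaction steps from
  existing members, and lattice-completing "densify" steps (apply two of
  a member's incident differences in sequence), with a feedback rule
  holding the running mean degree at the target. Target masses follow a
  truncated lognormal (median ≈ 280 Da) — serum metabolite masses
  concentrate in the low hundreds of Da rather than spreading uniformly
  to 800.
* **Truths**: 200 metabolites. 70% are universe members drawn with
  probability proportional to node degree — reference standards and
  abundant endogenous compounds are metabolites embedded in known
  biochemistry, not uniform draws from a formula list. The remaining 30%
  are novel: absent from the universe but constructed as double
  modifications $x + d_1 + d_2$ whose single-modification relatives
  $x + d_1$ and $x + d_2$ are both known — the family-embedded character
  of real unknowns (acylated, hydroxylated, conjugated variants of known
  compounds), giving reaction-adjacency to the seed set by construction.
* **Measurement model**: multiplicative Gaussian mass error with
  `ppm_sd = 0.7` (observed DI-HRMS calibration errors cluster near zero,
  well inside 2 ppm); M+1 peaks at the predicted shell intensity with 20%
  CV; 500 uniform noise peaks per sample, two thirds of which fall below
  the S/N filter; 25 blank contaminants present in blanks and samples
  alike; three IS ions in every sample; 3 biological samples (30%
  intensity CV), 2 blanks and 3 QC replicates (5% CV); peaks duplicated
  into overlapping windows so that stitching is always exercised.

What the generator deliberately does **not** model: ionization-efficiency
and matrix effects, in-source fragmentation, charge states beyond +1,
profile-mode peak shapes, centroiding artifacts, and mass-accuracy drift
across the run. A passing validation therefore demonstrates the
correctness and discriminative power of the *assignment machinery* under
realistic mass error, isotope noise and network structure — it does not
certify performance on any particular instrument or matrix, where adduct
frequencies, contaminant chemistry and the match between the real
metabolome and the seed database dominate.

## Evaluation

`coverage_accuracy()` counts coverage = uniquely assigned truth features
/ all truth features, and accuracy = correct (formula *and* adduct) /
uniquely assigned — the convention in which 95 unique of 96 features is
98.96% coverage and 89 correct of those 95 is 93.68% accuracy.
`target_decoy()` submits known and mass-matched decoy formulas to the
degree filter and compares pass rates; decoys are random valid formulas
excluded from the universe (an external decoy compound library would add
a dependency without changing the logic of the evaluation).
`database_search_baseline()` is the conventional alternative: count seed
ions within tolerance, unique iff exactly one match.

At the default study conditions the test suite requires mean coverage
≥ 95% and accuracy ≥ 90% over five seeded replicates, a rising
decoy-pass-rate with nested universe sizes (500/2000/8000) that stays
below the known rate, and strictly more unique network assignments than
database-search assignments when 30% of truths are novel. The
`scripts/acceptance.R` script recomputes these quantities from scratch.

## Numerical and degenerate-case choices

* Masses and abundances are pinned in-repo (AME2020 / IUPAC-CIAAW 2021,
  ≥ 6 decimals) so results cannot drift with external tables.
* Enumeration bounds use an epsilon of 1e-9 Da on window comparisons;
  completeness against a naive nested-loop oracle is part of the test
  suite.
* Score ties are broken by *not* assigning (deferral), never by index
  order; determinism under candidate-order permutation is tested.
* An empty candidate set, a feature with no connected candidate, blank
  intensity 0 (feature kept), QC mean 0 (RSD undefined, feature
  dropped), and a missing experimental M+1 (isotope score 0) are all
  defined outcomes, not errors.
* `blank_reduction()` requires at least one blank; `rsd_qc_filter()`
  at least two QCs; `normalize_by_is()` fails naming the sample and IS
  when a standard is missing — these are input errors a user must see.

## Problem sizes used in the tests

The validation suite runs at deliberately desk-scale sizes chosen to
exercise every code path with comfortable statistical margins: oracle
equivalence on 50 random m/z values and a 500-seed network, parameter
recovery on five 2000-seed / 200-truth studies, target-decoy curves up to
an 8000-formula universe, and hand-computable micro-fixtures for every
scoring and preprocessing rule. Production-scale inputs (10⁴–10⁵ seed
formulas, thousands of features) run through the same code; the
enumeration kernel is compiled and network matching is hash-based, so
both scale linearly in practice.

## Known limitations

* Only +1 positive-mode adducts; no negative mode, multimers or
  multiply charged species.
* The reaction table is unordered and unweighted; no directionality,
  stoichiometry or pathway context (global network optimization in the
  style of ILP-based annotators is out of scope).
* Isotope evidence uses the M+1 shell only; M+2 (chlorine/sulfur-rich
  chemistry) is predicted but not scored.
* De-isotoping is heuristic; a real M+1 feature whose parent falls below
  the noise filter will survive as a spurious feature (it cannot,
  however, claim a truth feature's identity in evaluation).
* Accuracy degrades with mass, as the candidate density inside a fixed
  ppm window grows roughly exponentially; above ~600 Da additional
  evidence (MS/MS, finer isotope structure) would be needed.
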