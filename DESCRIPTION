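Package: formnet
Title: Database-Independent Molecular Formula Assignment for
    Direct-Infusion HRMS via Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns molecular formulas to monoisotopic features from
    direct-infusion high-resolution mass spectrometry without relying on a
    compound database lookup alone. Candidate CHNOPS formulas are enumerated
    exhaustively within a ppm mass tolerance, filtered by their connectivity
    to a reaction network seeded with known metabolite formulas (edges are
    predefined biochemical formula differences), ranked by a weighted score
    combining network degree, mass accuracy and isotopic-pattern similarity,
    and assigned over multiple rounds in which newly assigned formulas join
    the seed network. Includes spectral-stitching window merging, peak
    alignment, blank reduction, internal-standard normalization and QC
    filtering for feature-table construction, a synthetic-study generator
    with ground truth, and target-decoy plus database-search evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
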