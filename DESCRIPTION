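Package: regufoot
Title: Comparative-Genomics Reconstruction of Bacterial Regulons by
    Phylogenetic Footprinting and Motif Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs transcription-factor regulons across sets of
    related annotated bacterial genomes. Implements reciprocal-best-hit
    orthology at a configurable identity threshold, upstream-region
    extraction, phylogenetic footprinting (progressive alignment of
    orthologous upstream regions and detection of conservation islands),
    discovery of spaced direct-repeat (dyad) motifs by seeded greedy
    refinement and of palindromic motifs by symmetry-constrained
    expectation maximization, position-weight-matrix construction and
    genome scanning with a training-set minimum-score threshold,
    cross-genome consistency-check filtering with operon inheritance,
    iterative regulon refinement, and motif similarity clustering.
    Ships a synthetic multi-genome benchmark generator with planted
    binding sites and a ground-truth manifest, plus packaged census
    tables for fixture-level checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
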