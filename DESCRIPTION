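Package: pts1var
Title: Mining Missense Variants that Create or Destroy Peroxisomal Targeting Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scanning population-scale variant catalogues for single
    nucleotide variants (SNVs) that hit the last three codons of protein-coding
    transcripts and thereby destroy an existing C-terminal peroxisomal targeting
    signal 1 (PTS1) or create one de novo on a cytosolic protein. Provides
    transcript validation against a genome, strand-aware mapping of SNVs onto
    C-terminal tripeptides, position-specific scoring of 12-residue C-termini
    with configurable targeting thresholds, loss-of-function and
    gain-of-function candidate filter cascades with per-stage accounting,
    concordance statistics between predicted and experimentally measured
    receptor-binding changes, and a deterministic synthetic-data generator so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    yaml,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
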