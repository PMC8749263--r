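Package: mitoring
Title: Circular Mitogenome Amplicon Design, Mitochondrial-Derived Peptide
    Prediction and Divergence Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with circular vertebrate mitogenomes as rings:
    in-silico PCR with back-to-back primer pairs (mismatch- and indel-tolerant
    semi-global scanning, single near-full-circle amplicon prediction, and
    primer design from conserved alignment windows), discovery and
    classification of short open reading frames encoding mitochondrial-derived
    peptides (MOTS-c, humanin, SHLP1-6 and gau) under configurable genetic
    codes and start-codon policies, uncorrected pairwise divergence with
    control-region exclusion and Genetic Species Concept flagging, screening
    of candidate cold-adaptation amino-acid sites, and a fully seeded
    synthetic-mitogenome generator that plants primer footprints, sORFs,
    control-region repeats and haplotype pairs of controlled divergence so
    that every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    BiocGenerics,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
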