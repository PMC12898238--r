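Package: splicecase
Title: Consequence Analysis of Splice-Acceptor Variants and Genome-Editing
    Feasibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes monogenic splice-acceptor single-nucleotide
    variants from sequence alone: maps HGVS c. coordinates to genomic
    positions, scans for the cryptic AG acceptor activated when the
    canonical site is disrupted, reconstructs the mutant transcript and
    derives the frameshift, premature termination codon,
    nonsense-mediated-decay prediction and truncated-peptide properties,
    detects CpG dinucleotides created or destroyed by an allele, evaluates
    therapeutic base-editing feasibility including pathogenic bystander
    edits and simplified prime-editing designs, and provides the cohort
    z-score and 2^-delta-delta-Ct expression statistics used to establish
    haploinsufficiency. Ships seeded synthetic-data generators with
    planted ground truth so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    rtracklayer,
    vcfR,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
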