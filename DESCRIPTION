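Package: guidebias
Title: Germline Variants in CRISPR Guide Targeting Sequences and Ancestry-Biased Screen Artifacts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and correcting ancestry-biased false negatives
    in genome-scale CRISPR viability screens caused by germline variants inside
    sgRNA targeting sequences. Implements window-based local ancestry assignment
    from reference-panel allele frequencies, ancestry-dependency association
    scans with lineage covariates, dependency-QTL scanning with
    Benjamini-Yekutieli correction, variant-to-guide mismatch mapping with
    PAM-relative positional effect estimation, per-cell-line guide-exclusion
    correction of gene-level dependency scores, and ancestry-aware guide
    selection under population allele-frequency constraints. A fully seeded
    synthetic-data generator (Balding-Nichols population panels, block-wise
    admixed diploid genomes on a genetic map, guide libraries and screens with
    injected mismatch artifacts) provides ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
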