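Package: cubkit
Title: Whole-Genome Codon Usage Bias Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for whole-genome codon usage bias analysis from a genome
    assembly (FASTA) and gene annotation (GFF3): spliced CDS extraction with
    quality filtering, per-gene codon metrics (RSCU, effective number of
    codons, CAI, CBI, Fop, positional GC), Nc-based bias stratification and
    optimal-codon identification, mutation-versus-selection diagnostics
    (Nc-GC3s expected curve, neutrality regression, parity rule 2),
    translational selection strength from two-fold degenerate amino acids
    (odds ratios, S and the codon-count-weighted genome statistic S-hat),
    tRNA anticodon adaptation with G:U wobble and inosine matching, and
    protein-domain versus non-domain optimal codon usage. Includes a seeded
    synthetic genome generator with known ground truth so the full pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
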