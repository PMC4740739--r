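Package: lgtscreen
Title: Windowed Homology Screening for Bacterial Lateral Gene Transfers in Draft Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects bacterial scaffolds and sub-scaffold bacterial insertions
    (lateral gene transfers, LGTs) in eukaryotic draft assemblies. Scaffolds are
    tiled into fixed-width windows and screened against a low-complexity-masked
    bacterial database with a seed-and-extend local aligner using
    Karlin-Altschul E-value statistics, counter-screened against an animal
    database, and the surviving bacterial-similar regions are joined and
    length-filtered into LGT candidates. Whole bacterial scaffolds
    (co-assembled endosymbionts or contaminants) are triaged separately by a
    per-scaffold best-hit comparison. Candidates are validated with
    junction-spanning read pairs and classified by RNA-seq coverage. A
    truth-tracked synthetic-genome simulator generates host scaffolds with
    implanted, partially decayed bacterial segments, contaminant scaffolds,
    junction-spanning mate pairs and coverage tracks for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    graphics,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
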