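Package: methylshift
Title: Differential DNA Methylation Calling and Polycomb Target Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline from methylation-enriched DNA measurements
    (MeDIP/MBD sequencing counts and tiling promoter-array probe scores) to
    gene-set over-representation statistics. Builds promoter/gene-body
    regions around transcription start sites, counts fragments per gene,
    calls per-gene differential methylation in a sequencing arm (pooled
    exact binomial against library-size proportion, Benjamini-Hochberg
    adjusted) and a replicate-concordance array arm, classifies directional
    responses to a paired knockdown/overexpression perturbation, and tests
    gene-list overlaps with the representation factor and the
    Yates-corrected chi-square alongside an exact hypergeometric test.
    Includes delta-delta-Ct qPCR quantification with Monte Carlo Dunnett
    comparisons, and a seeded synthetic-experiment generator with planted
    gene-set enrichment for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    BiocGenerics,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    optparse
Config/testthat/edition: 3
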