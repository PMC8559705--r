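Package: rdnarray
Title: Structure, Repeat Genotype and CpG Methylation of Ribosomal DNA
    Arrays from Nanopore Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Split-and-map analysis of tandem ribosomal DNA (rDNA) arrays
    from Oxford Nanopore long reads. Reads are split into fixed-length
    sections and mapped independently against a single repeat-unit
    reference, turning each read into a dot-plot-like alignment map.
    On top of that map the package screens reads for genuine rDNA array
    fragments (whole-genome or Cas9-enrichment mode), segments reads into
    rDNA copies, detects large structural deviations while suppressing
    natural satellite-length variation, triages palindromic reads into
    template-switch artifacts versus candidate real inversions, genotypes
    the intergenic-spacer R and Butterfly/Long repeats by anchor mapping,
    profiles per-copy CpG methylation from modified-base posteriors, and
    estimates rDNA copy number and the constant-active-copy relationship.
    A fully seeded synthetic-data generator (arrays, Nanopore-like errors,
    template-switch artifacts, bimodal methylation posteriors) makes every
    stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
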