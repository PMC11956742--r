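Package: naptp
Title: Six-Frame Non-Exon Proteogenomic Databases and Verification of
    Nascent Pioneer Translation Products
Version: 0.1.0
Authors@R:
    person("naptp", "maintainers", email = "naptp@example.org",
           role = c("aut", "cre"))
Description: Builds sample-specific six-frame non-exon (intronic)
    proteogenomic databases (SFDB) from a reference genome, a gene
    annotation and called variants, and verifies mass-spectrometry
    candidate peptides as nascent pioneer translation products
    (Na-PTPs): unique non-exonic genomic origin, sense or antisense
    orientation relative to the host gene, flanking residues and
    tryptic context, minimal product length, and enumeration of
    8-14-mer MHC-I epitope candidate windows for external binding
    predictors.  Ships a deterministic synthetic fixture generator so
    the whole pipeline is testable without any external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    optparse,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
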