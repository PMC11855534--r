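Package: cpcodon
Title: Codon Usage Bias and Structural Analysis of Chloroplast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of annotated plastomes: GenBank flat-file
    parsing and coding-sequence extraction, rule-based CDS filtering,
    relative synonymous codon usage (RSCU), positional GC content, observed
    and expected effective number of codons (ENc), codon adaptation index
    (CAI), ENc-plot, PR2-bias plot, GC12-GC3 neutrality regression,
    correspondence analysis of RSCU, optimal-codon identification from
    ENc-extreme gene libraries, microsatellite (SSR) and dispersed long
    repeat detection, and quadripartite (LSC/IRb/SSC/IRa) structure and
    junction reporting.  Includes a seeded synthetic plastome generator so
    every stage can be exercised against known ground truth without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
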