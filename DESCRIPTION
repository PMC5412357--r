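Package: mitocomp
Title: Comparative Analysis of Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated insect mitochondrial
    genomes: reading and writing GenBank flat files and feature tables, base
    composition and AT/GC strand-skew statistics, codon-position composition,
    start/stop codon tabulation and relative synonymous codon usage (RSCU)
    under the invertebrate mitochondrial code, extraction and IUPAC-ambiguity
    consensus of conserved intergenic spacers, tRNA cloverleaf stem mismatch
    detection and five-way classification of stem base-pair substitutions
    (compensatory, hemi-compensatory, reparative, mirrored, non-reparative),
    alignment conservation and A+T profiling, control-region
    structural-element detection (homopolymer stretches, (TA)n stretches,
    non-tandem macro repeats, stem-loops), and assembly of codon-position
    partitioned phylogenetic supermatrices. A seeded synthetic-genome
    generator with a machine-readable truth sidecar makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
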