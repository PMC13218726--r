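Package: karyocourt
Title: Adjudication of Discordant Chromosome Counts Between Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decide whether discordant chromosome-scale scaffold
    counts between two genome assemblies of the same species reflect real
    karyotypic differences or repeat-driven assembly artifacts. Implements
    trans Hi-C contact-rate statistics with empirical p-values against a
    genome-wide background, breakpoint detection from whole-genome
    alignments, read-depth and repeat-landscape evidence at scaffold
    junctions, coverage-based sex-chromosome identification for ZZ/Z0
    systems, a qPCR delta-Cq sex classifier, and a seeded synthetic-data
    generator emulating the statistical structure of Hi-C, depth, and
    repeat data so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
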