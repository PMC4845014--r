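Package: repmeth
Title: Repeat-Element DNA Methylation Analysis from Bisulphite Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of repeat-element DNA methylation from whole-genome
    bisulphite sequencing count tables in a two-sample (wild type versus
    mutant) design. Provides readers for per-cytosine reports and coverage
    files, strand merging of CpG dinucleotide calls, binomial library-size
    equalization, coverage-weighted methylation scoring of repeat elements
    and genome windows, imprinting-control-region purity summaries,
    percentage-point differential-methylation calling with subfamily
    enrichment tables and Mann-Whitney shift tests, clone-based Sanger
    bisulphite analysis with conversion-rate quality control, coat-colour
    penetrance statistics for metastable epialleles, and a seeded
    beta-binomial methylome simulator with planted effects and truth tables
    for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
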