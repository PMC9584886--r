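Package: skimseqr
Title: Skim-Sequencing Genotyping, Karyotyping and Introgression Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for very low-coverage ("skim") whole-genome sequencing of
    large plant populations. Covers combinatorial dual-index demultiplexing
    with blank-well quality control, selection of uniquely mapped concordant
    read pairs from aligner output, normalized read counts in megabase bins,
    chromosome and arm-level dosage classification (euploid, monosomic,
    nullisomic, telosomic), alien chromosome addition detection, delimitation
    of interspecific translocation breakpoints on a concatenated hybrid
    reference, sparse genotyping of doubled-haploid populations at parental
    SNPs with haplotype-block assignment, and a synthetic-data generator that
    emulates all of these inputs under known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    ggplot2,
    yaml,
    Biostrings,
    Rsamtools,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
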