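Package: hlacaller
Title: HLA Genotyping from Targeted Capture Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for typing the classical HLA loci from in-solution
    capture sequencing data. Provides capture bait panel design by
    non-overlapping tiling with iterative mismatch-tolerant gap filling,
    perfect-match read mapping against cDNA allele collections with
    exon-boundary truncated alignments, unique start-point coverage
    profiles, coverage- and central-read-based candidate filtering, and
    exhaustive allele-pair genotype calling ranked by a weighted harmonic
    mean of five mapping-derived parameters (allele-specific mappings,
    read equality, mappable sequence length, mapped pairs per read and
    coverage area under the curve). Includes a synthetic IMGT-style
    reference and paired-end read simulator, a diversity-maximising
    benchmark panel selector, QC tables with ambiguity reporting, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Biostrings,
    BiocGenerics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
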