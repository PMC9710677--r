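Package: telomotif
Title: Telomere Content Estimation from Whole-Genome Sequencing BAM Files
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies telomeric repeat content from duplicate-marked,
    coordinate-sorted whole-genome sequencing BAM files using a two-stage
    motif matcher: a fast exact-substring gate for runs of the canonical
    telomere hexamer (TTAGGG and its reverse complement) followed by a
    regular-expression confirmation that tolerates variation in the first
    three bases of each repeat unit. Scanning is restricted to user-defined
    genomic regions plus unmapped reads for speed, with a whole-file mode
    available as a validation oracle. Produces depth-normalised telomere
    content estimates (telomeric reads per million records) and tumour/normal
    log2 content ratios, driven by an INI-style configuration file, with JSON
    and TSV reports. Includes a synthetic SAM/BAM fixture generator with
    analytically known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    Biostrings,
    jsonlite,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
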