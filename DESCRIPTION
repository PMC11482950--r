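Package: torsionmap
Title: Genome-Wide DNA Torsion Mapping from Psoralen Crosslink Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts trimethylpsoralen (TMP) interstrand-crosslink
    sequencing coverage into a signed genome-wide torsion signal by
    subtracting a zero-torsion baseline measured on fixed, digested
    chromatin. Provides binned genomic track arithmetic, crosslink
    coverage extraction from paired-end alignments, metagene composite
    matrices (anchored and length-rescaled), nearest-neighbour gene-pair
    configuration analysis, promoter-class insulation analysis, and
    cohesin-loop boundary analysis. Includes a synthetic-data generator
    implementing the twin-supercoiled-domain model of transcription so
    that every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    GenomicAlignments,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
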