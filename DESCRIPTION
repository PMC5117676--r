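Package: bessurvey
Title: BAC-End Sequence Survey of Genome Composition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genome surveys based on BAC-end sequences (BESs):
    quality and vector trimming of Sanger-style end reads, organelle
    screening, a repeat-element census with hierarchical classification,
    microsatellite (SSR) mining with motif canonicalization and length
    classes, coding-region and gene-content extrapolation from homology
    hits, Clarke-Carbon library coverage statistics, and paired-end
    microsynteny classification against reference genomes.  A synthetic
    data generator produces toy genomes, clone libraries and end reads
    with full truth tables so that every stage can be validated without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
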