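Package: rdnamap
Title: Input-Normalized Occupancy Mapping and Factor Kinetics on the
    Ribosomal DNA Repeat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-resolution ChIP-Seq occupancy analysis on a single
    ribosomal DNA (rDNA) repeat carried as an extra chromosome: a circular
    coordinate system with a displaced origin, read extension, per-base
    coverage, window smoothing, reads-per-million scaling and
    input-normalized enrichment tracks; exponential-release kinetics of the
    RNA polymerase I initiation factor Rrn3 (spatial decay length converted
    to a temporal half-life); feature-level enrichment summaries, windowed
    peak calls and ratio statistics; two-Gaussian densitometry of psoralen
    crosslinking gel lanes for the active rDNA fraction; and a seeded
    synthetic-data generator with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    graphics,
    IRanges,
    jsonlite,
    S4Vectors,
    minpack.lm,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
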