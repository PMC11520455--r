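Package: CladeSynteny
Title: Synteny Block Assembly and Depth Statistics from Liftover Alignments
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs multi-species synteny from pairwise liftover
    alignments in PSL format. Alignment fragments are chained under a
    configurable gap value, filtered by a length percentage of the query,
    and classified into primary, co-gene and secondary (paralogous)
    fragments per species; pairwise synteny links are built between
    species adjacent in the guide-tree display order. Also computes
    genome-wide per-base synteny depth with window, feature-class and
    gene-class summaries, PSL-based paralog scores with parent/daughter
    inference for gene duplications, duplication-event size statistics,
    and ships a coordinate-level clade simulator that provides ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    ape,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
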