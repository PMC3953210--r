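Package: svpairs
Title: Structural-Variant Discovery from Mate-Pair Read Clusters
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide discovery of balanced chromosome rearrangements
    (reciprocal translocations, pericentric and paracentric inversions) and
    large deletions from long-insert mate-pair sequencing libraries.
    Implements discordant read-pair classification against a 2x-median-insert
    distance cutoff, single-linkage clustering with a minimum-support rule,
    insert-size-bounded breakpoint-interval refinement, reciprocal-junction
    pairing, junction micro-indel reconciliation, disrupted-gene and
    fusion-transcript annotation, ISCN-style karyotype revision, and
    validation/enrichment quality metrics. A synthetic rearranged-genome and
    mate-pair library simulator with exact liftover ground truth makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    Rsamtools,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
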