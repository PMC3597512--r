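Package: pirna21
Title: Classification and Upstream-Motif Analysis of C. elegans 21U RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for meta-analysis of Caenorhabditis elegans 21U RNAs
    (piRNAs) from multi-library small RNA sequencing counts: a 3'-linker
    removal cascade, an exact/low-mismatch read mapper with best-stratum
    reporting, RPM normalization with multi-locus weighting, an integer
    Enrichment Score classifier of male/female germline enrichment with a
    Poisson randomization null for false discovery estimation, upstream
    core-motif scanning (consensus CTGTTTCA) with spacer-length analytics,
    minicluster grouping and pair-composition tests, mismatch-tolerant 21U
    target search with 22G RNA attribution and randomization tests, and
    strand-aware signal metaprofiles. Includes a synthetic-data generator
    that plants motif/21U cassettes in simulated genomes with known truth
    so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
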