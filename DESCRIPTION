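Package: mtfivec
Title: Calling m5C and f5C in Mitochondrial tRNA from miCLIP and
    Bisulfite-Family Sequencing
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring cytosine-5 modifications in mitochondrial
    tRNA from sequencing data. Implements truncation-based methylation-site
    calling for miCLIP libraries (split-UMI barcode parsing, PCR
    deduplication, adapter trimming, unique alignment, truncation-to-cytosine
    assignment, RPM normalisation and replicate filtering), conversion
    calling for bisulfite-family libraries (BS, RedBS and fCAB RNA-Seq),
    three-chemistry deconvolution of 5-methylcytosine (plus
    5-hydroxymethylcytosine) versus 5-formylcytosine at the mt-tRNA-Met
    wobble base C34, and per-gene CLIP enrichment testing with a
    negative-binomial exact test at fixed dispersion. A synthetic-data
    module generates ground-truthed molecule populations and FASTQ libraries
    with the statistical structure the analysis assumes, so every caller can
    be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    edgeR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
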