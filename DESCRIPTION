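Package: txerr
Title: Transcriptional Error Rate Estimation from Per-Site Base Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates transcriptional (mistranscription) error rates from
    circular-consensus (Cir-Seq style) per-site base-count tables. Assigns
    nucleotide loci to annotated genes, excludes loci in overlapping genes,
    constructs per-(locus, condition, substitution type) "possible error"
    records, removes error hotspots by an iterative cumulative-binomial
    outlier procedure, and fits an identity-link Poisson model of error
    counts with reads as exposure and fixed effects for substitution type,
    experimental condition and log10 protein abundance. Includes nested-model
    likelihood-ratio tests, abundance-binned rate summaries with binomial
    confidence intervals, and a seeded synthetic-data generator emulating the
    statistical structure of the real data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
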