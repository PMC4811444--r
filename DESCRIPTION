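Package: callaudit
Title: Callability Auditing of Targeted Amplicon Panels for BRCA Testing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Audits which catalogued BRCA1/BRCA2 variants an amplicon
    next-generation sequencing panel can actually detect. Every variant in a
    merged ClinVar/COSMIC-style catalogue is evaluated at its locus
    (hotspot-forced calling) and classified as automatically callable,
    requiring manual review, or uncallable, with machine-readable no-call
    reasons (coverage gaps, homopolymer indel context, strand bias, quality
    failures). The package computes per-gene panel sensitivity, plans Sanger
    rescue reactions for blind spots, classifies observed tumour/normal
    variants by mutation type, pathogenicity and germline or somatic origin,
    and simulates amplicon pileup data with a homopolymer-length-dependent
    indel error model for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
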