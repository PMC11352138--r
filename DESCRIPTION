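Package: rhdtyper
Title: In Silico Two-Stage Molecular RHD Blood Group Typing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and evaluates a two-stage molecular RHD typing scheme
    for transfusion medicine: allele-specific real-time PCR (sequence-specific
    priming) with melting-curve genotyping for the four regionally predominant
    variant alleles (weak D types 1-3 and DVII), followed by exon 1-10
    amplification triage and Sanger-style sequence-based typing of
    target-negative samples, ending in ISBT allele assignment and predicted
    phenotype. Includes a synthetic-data module that builds a 10-exon RHD gene
    model with registered primer binding sites, diploid sample fixtures
    (including a 24-sample external quality assessment panel), and simulated
    single-direction sequencing traces with Phred quality values, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    BiocGenerics,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
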