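Package: trnam1a
Title: Quantitative tRNA m1A58 Stoichiometry from Reverse-Transcription
    Misincorporation Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies N1-methyladenosine at tRNA position 58
    (m1A58) from demethylase-contrasted small-RNA sequencing libraries. The
    modification blocks Watson-Crick pairing and leaves a misincorporation
    signature during reverse transcription; the misincorporation rate at the
    canonical position-58 adenosine, compared between an untreated and an
    in-vitro demethylated arm, yields per-tRNA modification stoichiometry.
    Includes UMI-based PCR deduplication, a self-contained glocal aligner,
    per-position pileups, differential-methylation calling across
    conditions, ribosome-profiling quality control (P-site offset, 3-nt
    periodicity), RPKM/translation-efficiency computation, codon-content
    enrichment testing, and a fully seeded synthetic-data generator with
    machine-readable truth tables for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
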