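Package: natsir
Title: Prediction of Natural-Antisense-Transcript-Derived siRNAs from
    Small RNA and Degradome Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies natural antisense transcript (NAT) pairs and the small
    interfering RNAs derived from their double-stranded overlap regions
    (nat-siRNAs) using adapter-trimmed small RNA libraries, a reference
    transcriptome (FASTA, or GFF3 annotation plus genome) and, optionally, a
    degradome (PARE) library. The pipeline filters input reads, aligns them
    exactly to the transcriptome, reduces the candidate space via sRNA phase
    blocks and degradome-adjacent regions, validates candidate transcript
    pairs by local complementarity alignment and intermolecular duplex
    verification, classifies pairs as cis or trans with orientation and
    coverage categories, assigns each overlap-region sRNA to one of five
    biogenesis groups based on star-partner and degradome evidence, and
    profiles alignment distribution patterns and densities. A synthetic-data
    generator plants ground-truth NAT loci and simulated libraries for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
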