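Package: twinpzm
Title: Postzygotic Somatic Mutation Discovery and Mutational Signature
    Attribution in Monozygotic Twin Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects postzygotic somatic mutations (PZMs) between
    monozygotic co-twins from paired whole-genome genotype calls and
    characterizes their mutational process. Implements the full desk-scale
    workflow: per-genotype and per-variant quality filtering (depth,
    genotype quality, call rate, region masks, variant allele frequency),
    twin genotype concordance from a 3x3 genotype contingency matrix,
    discordant-genotype PZM extraction with germline-database exclusion,
    trinucleotide (96-motif) mutational spectrum construction, and
    likelihood-based attribution of spectra to reference mutational
    signatures with a sequencing-artefact correction pooled from
    low-concordance pairs. A seeded synthetic twin-cohort simulator with
    truth tables makes every stage testable without access to protected
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
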