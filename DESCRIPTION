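Package: basecomp
Title: Genome Nucleotide Composition Laws: Profiles, Conformity Tests, and
    Sequence Design
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes genome-wide base-composition profiles from FASTA
    assemblies and evaluates them against three composition laws: Chargaff
    base-pairing parity (P(A)=P(T), P(G)=P(C)), purine/pyrimidine balance
    (P(R)=P(Y)=50%), and the independence factorization of base proportions
    from GC content and purine content (P(G)=P(S)P(R) and companions).
    Provides a 2x2 chi-square test of the factorization, cohort-level
    regression diagnostics and composition-outlier ranking across genomes,
    and a seeded designer that synthesizes sequences with specified GC and
    purine content under the independence model. A command-line interface
    exposes the four workflows (compose, laws, cohort, design).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
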