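Package: poldiv
Title: Multilocus Polymorphism-to-Divergence Analysis for Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Population-genetic analysis of phased coding-sequence alignments from
    closely related species pairs: per-locus diversity summaries (segregating sites,
    Watterson's theta, nucleotide diversity, haplotype diversity, Tajima's D),
    Jukes-Cantor divergence, Nei-Gojobori synonymous/nonsynonymous statistics with
    sliding windows, linkage disequilibrium (Kelly's ZnS, Hudson-Kaplan Rm),
    McDonald-Kreitman and multilocus maximum-likelihood HKA selection tests,
    mismatch-distribution expansion fitting with Rogers-Harpending curves, and a
    coalescent-likelihood comparison of constant-size, bottleneck and selective-sweep
    models. Includes a codon-aware two-species coalescent simulator so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
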