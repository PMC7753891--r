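Package: bcassoc
Title: Candidate-Gene Association Analysis of Beta-Carotene in Milk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for candidate-gene association analysis of milk
    beta-carotene content in dairy cattle and buffalo. Implements genotype
    quality control (call-rate filtering, allele frequencies, breed-wise
    imputation), pairwise linkage disequilibrium r2 from unphased genotypes
    via a two-locus EM algorithm, a staged fixed-effects linear-model
    procedure with allele-substitution effects, gene-wise F-tests and the
    extreme-genotype contrast D = 2*sum(|beta|), from-scratch Gibbs samplers
    for Bayes A and Bayes Cpi whole-genome regression with posterior-
    probability inference, a prior-comparison simulation study, and a
    synthetic-data generator that emulates the multi-breed study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
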