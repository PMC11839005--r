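Package: plasmanet
Title: Integrative Mapping of Plasma Protein Regulation by cis-QTLs,
    Seed Genes and Gene-Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the genetic and transcriptional regulation
    of plasma protein levels across tissues. Implements cis-eQTL and cis-pQTL
    mapping by per-SNP linear regression in windows around transcription
    start sites, allelic-coherence classification of shared e/pQTLs,
    approximate-Bayes-factor colocalization of summary statistics, LD-pruned
    estimation of the protein variance explained by independent cis-SNPs,
    Spearman seed-gene association with Storey-Tibshirani q-values and a
    multivariate cross-tissue adjustment model, module-eigengene association
    with a permutation null, and a synthetic multi-tissue data generator with
    a planted truth table so the whole pipeline can be validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
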