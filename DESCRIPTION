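Package: lshmm
Title: Genotype Imputation from Genotype Likelihoods with the Diploid
    Li-Stephens Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Full-state-space diploid Li-Stephens haplotype-copying hidden
    Markov model for genotype imputation from genotype likelihoods, aimed at
    low-coverage and ancient DNA samples.  Implements the collapsed
    forward-backward recursion that is linear in the number of hidden states,
    one- and two-level checkpointing to trade recomputation for memory, a
    low-coverage read-thinning simulator with GATK-style genotype
    likelihoods, and a concordance evaluation protocol with GP filtering and
    minor-allele-frequency stratification.  Reads and writes VCF for
    reference panels, target likelihoods and imputed output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
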