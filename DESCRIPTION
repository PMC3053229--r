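Package: caninaASE
Title: Allele-Specific Transcription and Copy-Number Inference under Canina
    Meiosis in Polyploid Dogroses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying homeolog-specific transcription in sexually
    reproducing odd-ploid dogroses (Rosa sect. Caninae). Implements a forward
    simulator of the canina meiosis (two recombining bivalent chromosome sets,
    maternally transmitted univalents), a beta-binomial generator for
    pyrosequencing allele-frequency assays on genomic DNA and cDNA pools,
    collapsing of cloned sequences into allele consensi with PCR-chimera
    screening and diagnostic-SNP discovery, likelihood-based inference of
    integer per-allele genomic copy numbers under the copy-number null
    (expected diagnostic-base fraction k/ploidy), tests and fold-change
    estimates for allele-specific expression with a mixed-model ANOVA on
    replicate fractions, and molecular-evolution analyses of homeologous
    alleles (substitution counting, Nei-Gojobori dN/dS, Goldman-Yang codon
    maximum likelihood with one- and two-ratio models, Tajima relative rate
    tests with false-discovery-rate control).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
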