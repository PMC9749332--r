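Package: hrdscar
Title: Genomic Scar Scores for Homologous Recombination Deficiency from
    SNP Array Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of SNP-array derived genomic
    instability in tumors. Generates synthetic allele-specific copy-number
    profiles and marker-level log R ratio / B-allele frequency signals with
    tumor purity dilution, GC-content waves and noise; performs GC-wave
    correction, joint two-channel changepoint segmentation by exact
    penalized optimal partitioning, grid-search purity/ploidy fitting and
    integer allele-specific copy-number calling; computes the three genomic
    scar metrics (loss of heterozygosity, telomeric allelic imbalance,
    large-scale state transitions) and their HRD sum with the clinical
    cut-off of 42; and provides the concordance battery (AUROC with
    confidence intervals, area under the precision-recall curve with
    prevalence baseline, Spearman and Pearson correlations) together with a
    marker-downsampling experiment (14 proportions, 10 replicates, median
    summary).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pROC,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
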