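Package: synthassoc
Title: Coalescent Simulation of Synthetic Genome-Wide Associations from
    Rare Causal Variants
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation pipeline for studying "synthetic" association: the
    phenomenon by which one or several rare causal variants in a genomic
    region create genome-wide significant case-control association signals
    at much more common variants. Provides a Hudson-style coalescent
    simulator of haplotype panels with infinite-sites mutation and optional
    fragment-boundary recombination, a dominant penetrance disease model
    with case/control ascertainment, fast additive logistic-regression
    association scans with conditional (covariate) analysis, two-locus
    linkage-disequilibrium moment curves, and grid experiment runners that
    aggregate power, risk-allele-frequency, secondary-signal and
    causal-distance summaries. Includes VCF and PLINK-style exporters and
    JSON run manifests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
NeedsCompilation: yes
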