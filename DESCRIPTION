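Package: breedscan
Title: Population-Genetic Scans for Structured Inbred Breeding Germplasm
Version: 0.1.0
Authors@R: person("breedscan", "developers", role = c("aut", "cre"),
    email = "maintainers@breedscan.dev")
Description: Quality control, diversity summaries, outgroup-polarized site
    frequency spectra, haploid Weir-Cockerham F(ST) outlier scans with
    dropout bootstrapping, Bayesian estimation of population divergence
    from ancestral allele frequencies (Nicholson's c), pairwise haplotype
    sharing (PHS) selection scans, windowed identity-by-state sharing
    between populations, and the four-population f4 admixture test, for
    SNP genotype matrices of highly selfed crop accessions organized into
    hierarchically structured breeding populations. Includes a seeded
    synthetic-data generator with machine-readable ground truth for
    parameter-recovery testing and a pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
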