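Package: speciflow
Title: Coalescent Tests of Speciation History and Gene Flow Timing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the speciation history of closely related
    species complexes from multilocus sequence, SNP and quantitative-trait
    data. Provides a structured-coalescent simulator for multi-population
    isolation-with-migration demographies with epoch-restricted migration
    (zero, historical, constant and recent gene-flow scenarios), approximate
    Bayesian computation (rejection) model choice on F_ST summary statistics,
    the genealogical sorting index for timing gene flow on gene trees, a
    posterior-predictive minimum-distance test of hybridization versus
    incomplete lineage sorting, sequence and SNP diversity statistics with
    hierarchical AMOVA and pairwise F_ST, and Q_ST-F_ST comparisons of
    quantitative trait divergence against neutral expectations. A synthetic
    study generator emulates the sampling design of a multi-species karst
    herb complex so every stage of the pipeline can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    phangorn,
    withr,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'RcppExports.R'
    'demography.R'
    'coalsim.R'
    'popstats-snp.R'
    'popstats-seq.R'
    'amova.R'
    'fst.R'
    'abc.R'
    'accessors.R'
    'jml.R'
    'gsi.R'
    'io.R'
    'qstfst.R'
    'synthetic.R'
    'cli.R'
    'utils.R'
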