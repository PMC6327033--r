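Package: rumenMGWAS
Title: Metagenome-Wide Association and Cross-Population Prediction of Feed Efficiency from Rumen Contig Abundances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for associating rumen (or other shotgun) metagenome contig
    abundances with host feed-efficiency phenotypes in dairy cattle. Implements
    counts-per-million normalization and prevalence filtering of sample-by-contig
    abundance matrices, phenotype derivation (feed efficiency as milk yield over
    dry matter intake, residual feed intake as the residual of a within-population
    intake regression), a Gaussian-entropy information-gain pre-selection of
    contigs, per-contig logistic metaGWAS for HIGH versus LOW phenotype groups,
    hierarchical clustering of animals with multiscale-bootstrap BP and
    approximately unbiased (AU) cluster support, and cross-population phenotype
    prediction with an L1-penalized linear model evaluated against a
    random-contig resampling null distribution. A synthetic cohort generator
    with planted contig-phenotype signal makes the whole pipeline testable
    without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    ape,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'AbundanceMatrix.R'
    'RcppExports.R'
    'association.R'
    'cluster.R'
    'infogain.R'
    'lasso.R'
    'phenotypes.R'
    'pipeline.R'
    'simulate.R'
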