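#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#' @importFrom stats cor cov glm binomial quasibinomial lm coef cutree dist
#'   hclust median pnorm qnorm quantile rgamma rmultinom rnorm runif sd var
#'   dnorm as.dist setNames resid predict p.adjust complete.cases
#' @importFrom stats lm.fit lm.wfit
#' @importFrom utils head read.csv read.delim write.csv write.table
#' @importFrom Rcpp sourceCpp
#' @useDynLib rumenMGWAS, .registration = TRUE
NULL

setOldClass("hclust")

.ABUNDANCE_UNITS <- c("counts", "cpm", "relative")

#' AbundanceMatrix: a sample-by-contig abundance container
#'
#' An `AbundanceMatrix` holds one non-negative abundance assay with contigs
#' (features) in rows and animals (samples) in columns, following the usual
#' Bioconductor orientation, plus a declared unit: `"counts"` (raw mapped
#' read counts, e.g. the NumReads column of a quantifier output), `"cpm"`
#' (counts per million: each sample's values sum to 1e6), or `"relative"`
#' (each sample sums to 1).
#'
#' Validity enforces non-negativity, no missing values, unique feature and
#' sample identifiers, and the per-sample sum implied by the unit (within
#' relative tolerance 1e-6 for CPM, 1e-9 for relative abundances). After a
#' feature subset is taken (e.g. keeping only pre-selected contigs) the
#' per-sample sums no longer close to 1e6; such objects carry
#' `metadata(x)$feature_subset == TRUE` and the sum check is skipped while
#' the unit label is retained.
#'
#' @slot unit character(1), one of `"counts"`, `"cpm"`, `"relative"`.
#' @export
setClass("AbundanceMatrix",
  contains = "SummarizedExperiment",
  representation(unit = "character"),
  prototype(unit = "counts")
)

setValidity("AbundanceMatrix", function(object) {
  msg <- character()
  if (length(object@unit) != 1L || !(object@unit %in% .ABUNDANCE_UNITS))
    msg <- c(msg, sprintf("'unit' must be one of %s",
                          paste(.ABUNDANCE_UNITS, collapse = ", ")))
  if (length(assays(object)) < 1L)
    return(c(msg, "an abundance assay is required"))
  a <- assay(object)
  if (anyNA(a)) msg <- c(msg, "abundance values must not be missing (absence is 0)")
  else if (any(a < 0)) msg <- c(msg, "abundance values must be non-negative")
  if (anyDuplicated(rownames(a))) msg <- c(msg, "feature ids must be unique")
  if (anyDuplicated(colnames(a))) msg <- c(msg, "sample ids must be unique")
  subsetted <- isTRUE(metadata(object)$feature_subset)
  if (!anyNA(a) && !subsetted && ncol(a) > 0L) {
    cs <- colSums(a)
    if (object@unit == "cpm" && any(abs(cs - 1e6) > 1e-6 * 1e6))
      msg <- c(msg, "CPM samples must each sum to 1e6 (relative tolerance 1e-6)")
    if (object@unit == "relative" && any(abs(cs - 1) > 1e-9))
      msg <- c(msg, "relative-abundance samples must each sum to 1 (tolerance 1e-9)")
  }
  if (length(msg)) msg else TRUE
})

#' PhenotypeTable: per-animal production records
#'
#' A `DataFrame` subclass holding one row per animal with the production
#' records used to derive feed-efficiency phenotypes. Required columns:
#' `animal_id`, `milk_yield` (kg/d), `dmi` (dry matter intake, kg/d),
#' `body_weight` (kg), `parity` (`"primiparous"`/`"multiparous"`), and
#' `population`. Optional columns: `fat_pct`, `protein_pct`, and the derived
#' `fe` (milk_yield / dmi), `rfi` (kg/d, mean zero within population) and
#' `group` (`"HIGH"`, `"LOW"` or `"unassigned"`).
#'
#' @export
setClass("PhenotypeTable", contains = "DFrame")

.PHENO_REQUIRED <- c("animal_id", "milk_yield", "dmi", "body_weight",
                     "parity", "population")

setValidity("PhenotypeTable", function(object) {
  msg <- character()
  missing_cols <- setdiff(.PHENO_REQUIRED, colnames(object))
  if (length(missing_cols))
    return(sprintf("missing required columns: %s",
                   paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(object$animal_id)) msg <- c(msg, "animal_id must be unique")
  if (anyNA(object$milk_yield) || anyNA(object$dmi) || anyNA(object$body_weight))
    msg <- c(msg, "milk_yield, dmi and body_weight must not be missing")
  else {
    if (any(object$milk_yield < 0)) msg <- c(msg, "milk_yield must be >= 0")
    if (any(object$dmi <= 0)) msg <- c(msg, "dmi must be > 0")
    if (any(object$body_weight <= 0)) msg <- c(msg, "body_weight must be > 0")
  }
  if (!all(object$parity %in% c("primiparous", "multiparous")))
    msg <- c(msg, "parity must be 'primiparous' or 'multiparous'")
  if ("fe" %in% colnames(object) && !anyNA(object$fe)) {
    ok <- abs(object$fe - object$milk_yield / object$dmi) <=
      1e-8 * pmax(1, abs(object$fe))
    if (!all(ok)) msg <- c(msg, "fe must equal milk_yield / dmi")
  }
  if ("rfi" %in% colnames(object) && !anyNA(object$rfi)) {
    mu <- tapply(object$rfi, object$population, mean)
    if (any(abs(mu) > 1e-9 * pmax(1, tapply(abs(object$rfi), object$population, max))))
      msg <- c(msg, "rfi must average zero within each population")
  }
  if ("group" %in% colnames(object) &&
      !all(object$group %in% c("HIGH", "LOW", "unassigned")))
    msg <- c(msg, "group must be 'HIGH', 'LOW' or 'unassigned'")
  if (length(msg)) msg else TRUE
})

#' Simulation settings for paired reference/validation cohorts
#'
#' Holds the study-design parameters emulated by [simulateCohorts()]:
#' cohort sizes, number of contigs, number of contigs carrying a planted
#' phenotype effect, the standardized log-abundance shift between HIGH and
#' LOW latent classes, the fraction of planted effects that persist in the
#' validation population, negative-binomial overdispersion, per-sample
#' library-size range, the fraction of reference contigs quantifiable in
#' the validation cohort, and the RNG seed.
#'
#' @export
setClass("SimulationConfig",
  representation(
    nRef = "integer", nVal = "integer", nContigs = "integer",
    nInformative = "integer", effectSize = "numeric",
    sharedFraction = "numeric", dispersion = "numeric",
    librarySizeRange = "numeric", mappedFraction = "numeric",
    feClassMeans = "numeric", feSd = "numeric", rngSeed = "integer"
  ),
  prototype(
    nRef = 30L, nVal = 31L, nContigs = 2000L, nInformative = 50L,
    effectSize = 1.5, sharedFraction = 0.6, dispersion = 0.5,
    librarySizeRange = c(1e5, 3e5), mappedFraction = 0.85,
    feClassMeans = c(high = 1.5, low = 1.1), feSd = 0.156, rngSeed = 1L
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nInformative > object@nContigs)
    msg <- c(msg, "nInformative must not exceed nContigs")
  if (object@sharedFraction < 0 || object@sharedFraction > 1)
    msg <- c(msg, "sharedFraction must be in [0, 1]")
  if (!is.finite(object@effectSize)) msg <- c(msg, "effectSize must be finite")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (length(object@librarySizeRange) != 2L ||
      any(object@librarySizeRange < 1) ||
      diff(object@librarySizeRange) < 0)
    msg <- c(msg, "librarySizeRange must be an increasing pair of sizes >= 1")
  if (object@librarySizeRange[1] < object@nContigs)
    msg <- c(msg, "library sizes must be at least nContigs for a usable depth")
  if (object@mappedFraction <= 0 || object@mappedFraction > 1)
    msg <- c(msg, "mappedFraction must be in (0, 1]")
  if (object@nRef < 4L || object@nVal < 3L)
    msg <- c(msg, "cohorts must contain at least a few animals")
  if (length(msg)) msg else TRUE
})

#' Pipeline settings
#'
#' Centralizes the pipeline constants: the prevalence threshold (minimum
#' number of samples a contig must be observed in), the information-gain
#' selection percentile, the metaGWAS significance level, the number of
#' random-contig null replicates, the root RNG seed, and the LASSO penalty
#' strategy (`"cv"` for cross-validated, `"fixed"` with `lambdaValue`).
#'
#' @export
setClass("PipelineConfig",
  representation(
    minPrevalence = "integer", igPercentile = "numeric", alpha = "numeric",
    nNullReplicates = "integer", rngSeed = "integer",
    lambdaStrategy = "character", lambdaValue = "numeric",
    bootScales = "numeric", nBootReplicates = "integer"
  ),
  prototype(
    minPrevalence = 7L, igPercentile = 95, alpha = 0.05,
    nNullReplicates = 1000L, rngSeed = 1L,
    lambdaStrategy = "cv", lambdaValue = NA_real_,
    bootScales = seq(0.5, 1.4, by = 0.1), nBootReplicates = 1000L
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@minPrevalence < 1L) msg <- c(msg, "minPrevalence must be >= 1")
  if (object@igPercentile <= 0 || object@igPercentile >= 100)
    msg <- c(msg, "igPercentile must lie in (0, 100)")
  if (object@alpha <= 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in (0, 1]")
  if (object@nNullReplicates < 1L) msg <- c(msg, "nNullReplicates must be >= 1")
  if (!(object@lambdaStrategy %in% c("cv", "fixed")))
    msg <- c(msg, "lambdaStrategy must be 'cv' or 'fixed'")
  if (object@lambdaStrategy == "fixed" &&
      (is.na(object@lambdaValue) || object@lambdaValue <= 0))
    msg <- c(msg, "lambdaStrategy 'fixed' requires lambdaValue > 0")
  if (length(msg)) msg else TRUE
})

#' Hierarchical clustering of animals with multiscale-bootstrap support
#'
#' Wraps an average-linkage (UPGMA) dendrogram over animals, built on
#' correlation distance between contig-abundance profiles, together with a
#' per-edge table of bootstrap probabilities (BP) by resampling scale and
#' approximately unbiased (AU) p-values obtained by probit extrapolation
#' across scales. Before [multiscaleBootstrap()] has been run the edge
#' table carries only the leaf-set signatures.
#'
#' @slot hclust the underlying [stats::hclust] object.
#' @slot leafIds animal identifiers, in input order.
#' @slot edges a `DataFrame` with one row per internal edge: `node`,
#'   `signature` (sorted leaf ids joined by `"|"`), `n_leaves`, `height`,
#'   and after bootstrapping `bp1`, `au`, `fit_rss`, `fit_df`, `flag`,
#'   plus a `bp_by_scale` matrix in `metadata()`.
#' @slot scales numeric vector of resampling scale ratios (empty before
#'   bootstrapping).
#' @slot nboot bootstrap replicates per scale.
#' @slot seed RNG seed used for resampling.
#' @export
setClass("SupportedDendrogram",
  representation(
    hclust = "hclust", leafIds = "character", edges = "DFrame",
    scales = "numeric", nboot = "integer", seed = "integer"
  )
)

setValidity("SupportedDendrogram", function(object) {
  msg <- character()
  n <- length(object@leafIds)
  if (n < 2L) msg <- c(msg, "at least two leaves are required")
  if (nrow(object@edges) != n - 1L)
    msg <- c(msg, "edge table must have one row per internal node")
  if (is.unsorted(object@hclust$height))
    msg <- c(msg, "merge heights must be non-decreasing (ultrametric linkage)")
  if ("au" %in% colnames(object@edges)) {
    au <- object@edges$au
    if (any(!is.na(au) & (au < 0 | au > 1)))
      msg <- c(msg, "AU values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Accuracy of a dendrogram cut against known group labels
#'
#' @slot k number of clusters the tree was cut into.
#' @slot predicted named integer cluster per animal.
#' @slot labels the truth labels used.
#' @slot accuracy best concordant fraction over cluster-to-label assignments.
#' @slot table the cluster-by-label contingency table.
#' @export
setClass("ClusterAccuracyReport",
  representation(k = "integer", predicted = "integer", labels = "character",
                 accuracy = "numeric", table = "table")
)

setValidity("ClusterAccuracyReport", function(object) {
  if (object@accuracy < 0 || object@accuracy > 1)
    "accuracy must lie in [0, 1]" else TRUE
})

#' L1-penalized linear model for metagenomic phenotype prediction
#'
#' Stores the fit of `y = y0 + X beta + e` minimizing
#' `0.5 * ||y - y0 - X beta||^2 + n * lambda * ||beta||_1`
#' by cyclic coordinate descent, together with the training feature universe
#' and the per-feature standardization parameters needed to predict new
#' animals on the original CPM scale.
#'
#' @slot intercept adjusted population mean `y0`.
#' @slot coefficients named numeric of nonzero coefficients on the original
#'   feature scale (zero coefficients omitted).
#' @slot lambda the penalty used.
#' @slot nTrain training-set size.
#' @slot featureIds all training feature ids (the prediction universe).
#' @slot center,scale per-feature standardization parameters.
#' @slot standardized whether features were standardized for the fit.
#' @slot residualSd maximum-likelihood SD of training residuals.
#' @export
setClass("LassoModel",
  representation(
    intercept = "numeric", coefficients = "numeric", lambda = "numeric",
    nTrain = "integer", featureIds = "character",
    center = "numeric", scale = "numeric", standardized = "logical",
    residualSd = "numeric"
  )
)

setValidity("LassoModel", function(object) {
  msg <- character()
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (!all(names(object@coefficients) %in% object@featureIds))
    msg <- c(msg, "coefficients must refer to training features")
  if (length(msg)) msg else TRUE
})

#' Null distribution of predictive accuracy from random contig subsets
#'
#' @slot accuracies Pearson validation accuracies, one per replicate.
#' @slot subsetSize number of contigs drawn per replicate.
#' @slot observed the observed accuracy of the selected-contig model.
#' @slot seed RNG seed.
#' @export
setClass("NullDistribution",
  representation(accuracies = "numeric", subsetSize = "integer",
                 observed = "numeric", seed = "integer")
)

setValidity("NullDistribution", function(object) {
  acc <- object@accuracies[!is.na(object@accuracies)]
  if (length(acc) && (min(acc) < -1 - 1e-12 || max(acc) > 1 + 1e-12))
    "replicate accuracies must lie in [-1, 1]" else TRUE
})

#' Manifest of a full pipeline run
#'
#' Records everything needed to reproduce a run: the configuration
#' snapshot, the per-stage derived seeds, the feature funnel (features in,
#' after the prevalence filter, after information-gain selection, after the
#' significance threshold), and any files written.
#'
#' @export
setClass("RunManifest",
  representation(config = "list", seeds = "integer", counts = "integer",
                 outputs = "character")
)

setValidity("RunManifest", function(object) {
  cn <- c("n_features", "after_prevalence", "after_infogain", "significant")
  if (!all(cn %in% names(object@counts)))
    return("counts must include the full filter funnel")
  x <- object@counts[cn]
  if (any(diff(x) > 0))
    "funnel counts must be non-increasing across stages" else TRUE
})
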