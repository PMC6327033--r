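#' @include AllClasses.R
NULL

#' @rdname AbundanceMatrix-class
#' @param x an object.
#' @export
setGeneric("abundanceUnit", function(x) standardGeneric("abundanceUnit"))

#' @rdname AbundanceMatrix-class
#' @export
setGeneric("abundanceValues", function(x) standardGeneric("abundanceValues"))

#' @rdname AbundanceMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname AbundanceMatrix-class
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname cpmNormalize
#' @export
setGeneric("cpmNormalize", function(x, ...) standardGeneric("cpmNormalize"))

#' @rdname prevalenceFilter
#' @export
setGeneric("prevalenceFilter",
           function(x, minCount, ...) standardGeneric("prevalenceFilter"))

#' @rdname SupportedDendrogram-class
#' @param x an object.
#' @export
setGeneric("clusterEdges", function(x) standardGeneric("clusterEdges"))

#' @rdname NullDistribution-class
#' @param x an object.
#' @export
setGeneric("replicateAccuracies",
           function(x) standardGeneric("replicateAccuracies"))

#' @rdname NullDistribution-class
#' @export
setGeneric("observedAccuracy", function(x) standardGeneric("observedAccuracy"))

#' @rdname NullDistribution-class
#' @export
setGeneric("percentileRank", function(x) standardGeneric("percentileRank"))
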