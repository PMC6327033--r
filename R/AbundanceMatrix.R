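#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an AbundanceMatrix
#'
#' @param values numeric matrix of abundances with contigs in rows and
#'   samples in columns. Row and column names supply the identifiers; if
#'   absent, `featureIds`/`sampleIds` must be given.
#' @param unit `"counts"`, `"cpm"` or `"relative"`.
#' @param featureIds,sampleIds optional identifier vectors overriding the
#'   dimnames of `values`.
#'
#' @return an [AbundanceMatrix-class] object.
#' @examples
#' m <- AbundanceMatrix(matrix(rpois(20, 50), nrow = 4,
#'                             dimnames = list(paste0("c", 1:4),
#'                                             paste0("cow", 1:5))),
#'                      unit = "counts")
#' abundanceUnit(m)
#' @export
AbundanceMatrix <- function(values, unit = c("counts", "cpm", "relative"),
                            featureIds = NULL, sampleIds = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (!is.null(featureIds)) rownames(values) <- featureIds
  if (!is.null(sampleIds)) colnames(values) <- sampleIds
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("feature_%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("sample_%d", seq_len(ncol(values)))
  storage.mode(values) <- "double"
  se <- SummarizedExperiment(assays = SimpleList(abundance = values))
  new("AbundanceMatrix", se, unit = unit)
}

#' @rdname AbundanceMatrix-class
#' @export
setMethod("abundanceUnit", "AbundanceMatrix", function(x) x@unit)

#' @rdname AbundanceMatrix-class
#' @export
setMethod("abundanceValues", "AbundanceMatrix", function(x) assay(x, "abundance"))

#' @rdname AbundanceMatrix-class
#' @export
setMethod("sampleIds", "AbundanceMatrix", function(x) colnames(x))

#' @rdname AbundanceMatrix-class
#' @export
setMethod("featureIds", "AbundanceMatrix", function(x) rownames(x))

setMethod("show", "AbundanceMatrix", function(object) {
  cat(sprintf("AbundanceMatrix [%s]: %d features x %d samples\n",
              object@unit, nrow(object), ncol(object)))
  a <- assay(object)
  cat(sprintf("  sparsity: %.1f%% zero entries\n", 100 * mean(a == 0)))
  if (isTRUE(metadata(object)$feature_subset))
    cat("  feature subset of a larger matrix (per-sample totals not closed)\n")
})

# Mark a feature subset so the unit sum invariant is relaxed but the unit
# label (the scale the values are on) is retained.
.subsetFeatures <- function(x, keep) {
  out <- x[keep, ]
  metadata(out)$feature_subset <- TRUE
  validObject(out)
  out
}

#' Counts-per-million normalization
#'
#' Scales each sample (column) of a raw-count matrix so its values sum to
#' one million. Zeros are preserved; a sample with zero total counts is an
#' error because a library with no mapped reads is unusable.
#'
#' @param x an [AbundanceMatrix-class] with unit `"counts"`.
#' @param ... unused.
#' @return an [AbundanceMatrix-class] with unit `"cpm"`.
#' @examples
#' m <- AbundanceMatrix(matrix(c(1, 3), nrow = 2), unit = "counts")
#' abundanceValues(cpmNormalize(m))  # 250000, 750000
#' @export
setMethod("cpmNormalize", "AbundanceMatrix", function(x, ...) {
  if (abundanceUnit(x) != "counts")
    stop("cpmNormalize() expects raw counts, got unit '", abundanceUnit(x), "'")
  a <- assay(x, "abundance")
  totals <- colSums(a)
  if (any(totals <= 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(a)[totals <= 0], collapse = ", "))
  out <- x
  assay(out, "abundance") <- sweep(a, 2, totals, "/") * 1e6
  out@unit <- "cpm"
  validObject(out)
  out
})

#' Prevalence filter
#'
#' Retains the features observed (nonzero) in at least `minCount` samples,
#' preserving feature order. The identifiers of dropped features are stored
#' in `metadata(result)$dropped_features`.
#'
#' @param x an [AbundanceMatrix-class].
#' @param minCount integer >= 1; a feature must be nonzero in at least this
#'   many samples to be kept. The default of 7 reflects a 7-of-30 design;
#'   `ceiling(0.25 * ncol(x))` gives the equivalent 25%-of-animals rule.
#' @param ... unused.
#' @return a filtered [AbundanceMatrix-class].
#' @export
setMethod("prevalenceFilter", "AbundanceMatrix", function(x, minCount = 7L, ...) {
  minCount <- as.integer(minCount)
  if (length(minCount) != 1L || is.na(minCount) || minCount < 1L)
    stop("minCount must be a single integer >= 1")
  if (minCount > ncol(x))
    stop("minCount (", minCount, ") exceeds the number of samples (", ncol(x), ")")
  prevalence <- rowSums(assay(x, "abundance") > 0)
  keep <- prevalence >= minCount
  out <- x[keep, ]
  metadata(out)$dropped_features <- rownames(x)[!keep]
  validObject(out)
  out
})

#' Dropped features of a prevalence-filtered matrix
#'
#' @param x an [AbundanceMatrix-class] returned by [prevalenceFilter()].
#' @return character vector of dropped feature ids.
#' @export
droppedFeatures <- function(x) {
  d <- metadata(x)$dropped_features
  if (is.null(d)) character() else d
}

#' Read and write sample-by-feature abundance tables
#'
#' The on-disk format is tab-separated text with one row per sample: the
#' first column holds the sample id and the header row names the features.
#' (In memory features are rows, following Bioconductor convention.)
#'
#' @param path file path.
#' @param unit declared unit of the stored values.
#' @return an [AbundanceMatrix-class].
#' @export
readAbundanceTable <- function(path, unit = c("counts", "cpm", "relative")) {
  unit <- match.arg(unit)
  tab <- read.delim(path, header = TRUE, row.names = 1, check.names = FALSE)
  AbundanceMatrix(t(as.matrix(tab)), unit = unit)
}

#' @rdname readAbundanceTable
#' @param x an [AbundanceMatrix-class] to write.
#' @export
writeAbundanceTable <- function(x, path) {
  tab <- t(assay(x, "abundance"))
  out <- data.frame(sample_id = rownames(tab), tab, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble an AbundanceMatrix from per-sample quantification tables
#'
#' Reads per-sample quantifier output tables (tab-separated with columns
#' `Name`, `Length`, `EffectiveLength`, `TPM`, `NumReads`, as written by
#' SALMON-style quantifiers) and assembles the `NumReads` columns into one
#' raw-count matrix. Features missing from a sample's table are recorded
#' as zero.
#'
#' @param paths character vector of file paths, one per sample.
#' @param sampleIds sample identifiers; defaults to the file base names.
#' @return an [AbundanceMatrix-class] with unit `"counts"`.
#' @export
readSalmonQuants <- function(paths, sampleIds = NULL) {
  if (is.null(sampleIds))
    sampleIds <- sub("\\.[^.]*$", "", basename(paths))
  stopifnot(length(sampleIds) == length(paths))
  tabs <- lapply(paths, function(p) {
    t <- read.delim(p, header = TRUE, check.names = FALSE)
    need <- c("Name", "NumReads")
    if (!all(need %in% colnames(t)))
      stop("quantification table ", p, " lacks columns: ",
           paste(setdiff(need, colnames(t)), collapse = ", "))
    t
  })
  features <- Reduce(union, lapply(tabs, `[[`, "Name"))
  values <- matrix(0, nrow = length(features), ncol = length(paths),
                   dimnames = list(features, sampleIds))
  for (i in seq_along(tabs))
    values[match(tabs[[i]]$Name, features), i] <- tabs[[i]]$NumReads
  AbundanceMatrix(values, unit = "counts")
}
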