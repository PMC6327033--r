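#' @include AllClasses.R AllGenerics.R
NULL

#' Pipeline settings constructor
#'
#' @param minPrevalence minimum number of samples a contig must be nonzero
#'   in (default 7, the 7-of-30 design; use `ceiling(0.25 * n)` for the
#'   25%-of-animals rule).
#' @param igPercentile information-gain selection percentile (default 95:
#'   keep the top 5%).
#' @param alpha metaGWAS significance level (default 0.05, uncorrected).
#' @param nNullReplicates random-contig null replicates (default 1000).
#' @param rngSeed root seed; per-stage seeds are derived from it.
#' @param lambdaStrategy `"cv"` or `"fixed"`.
#' @param lambdaValue penalty when `lambdaStrategy = "fixed"`.
#' @param bootScales,nBootReplicates multiscale-bootstrap settings.
#' @return a [PipelineConfig-class].
#' @export
PipelineConfig <- function(minPrevalence = 7L, igPercentile = 95,
                           alpha = 0.05, nNullReplicates = 1000L,
                           rngSeed = 1L, lambdaStrategy = "cv",
                           lambdaValue = NA_real_,
                           bootScales = seq(0.5, 1.4, by = 0.1),
                           nBootReplicates = 1000L) {
  new("PipelineConfig", minPrevalence = as.integer(minPrevalence),
      igPercentile = igPercentile, alpha = alpha,
      nNullReplicates = as.integer(nNullReplicates),
      rngSeed = as.integer(rngSeed), lambdaStrategy = lambdaStrategy,
      lambdaValue = as.numeric(lambdaValue), bootScales = bootScales,
      nBootReplicates = as.integer(nBootReplicates))
}

#' Read a PipelineConfig (and optional SimulationConfig) from YAML
#'
#' The file may contain a `pipeline:` block with [PipelineConfig()] fields
#' and a `simulation:` block with [SimulationConfig()] fields. Unknown
#' fields are reported with their path before anything is computed.
#'
#' @param path YAML file path.
#' @return a list with elements `pipeline` and (if present) `simulation`.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  check_fields <- function(given, allowed, block) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop("unknown config field(s): ",
           paste(sprintf("%s.%s", block, bad), collapse = ", "))
  }
  out <- list()
  pl <- raw$pipeline
  if (is.null(pl)) pl <- list()
  check_fields(pl, names(formals(PipelineConfig)), "pipeline")
  out$pipeline <- do.call(PipelineConfig, pl)
  if (!is.null(raw$simulation)) {
    check_fields(raw$simulation, names(formals(SimulationConfig)), "simulation")
    out$simulation <- do.call(SimulationConfig, raw$simulation)
  }
  out
}

# One root seed, per-stage derived seeds (kept below 2^31) so any stage
# can be rerun in isolation with its own seed from the manifest.
.stageSeeds <- function(root) {
  stages <- c("simulate", "groups", "bootstrap", "lambda", "null")
  setNames(as.integer((as.numeric(root) * 7919 + seq_along(stages) * 104729)
                      %% .Machine$integer.max), stages)
}

#' @rdname RunManifest-class
#' @param x a [RunManifest-class].
#' @export
manifestCounts <- function(x) {
  stopifnot(is(x, "RunManifest"))
  x@counts
}

setMethod("show", "RunManifest", function(object) {
  cat("RunManifest\n  funnel:",
      paste(sprintf("%s=%d", names(object@counts), object@counts),
            collapse = " -> "), "\n")
  cat("  seeds:", paste(sprintf("%s=%d", names(object@seeds), object@seeds),
                        collapse = ", "), "\n")
  if (length(object@outputs))
    cat("  outputs:", paste(object@outputs, collapse = ", "), "\n")
})

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in the documented order: (optionally) simulate
#' -> prevalence-filter the raw counts -> CPM-normalize -> derive FE and
#' assign HIGH/LOW groups -> information-gain pre-selection -> per-contig
#' logistic metaGWAS -> hierarchical clustering of the reference animals
#' (optionally with multiscale-bootstrap support) -> L1-penalized
#' cross-population prediction -> random-contig null. Counts are filtered
#' before CPM normalization; no renormalization takes place after the
#' information-gain or significance subsets. A failing stage aborts with
#' the stage name.
#'
#' @param config a [PipelineConfig-class], or a YAML path readable by
#'   [readPipelineConfig()].
#' @param simConfig a [SimulationConfig-class] used to generate the
#'   cohorts (ignored when `data` is given).
#' @param data optionally, pre-built inputs: a list like the return value
#'   of [simulateCohorts()] (elements `ref`, `val`, each with `abundance`
#'   counts and `phenotypes`).
#' @param trait phenotype to analyse: `"fe"` (derived) or `"dmi"`.
#' @param nPerTail animals per extreme group (default half the reference
#'   cohort, i.e. 15 of 30).
#' @param bootstrap compute multiscale-bootstrap support (slower).
#' @param runNull compute the random-contig null distribution.
#' @param outdir optional directory; when given, stage outputs are written
#'   as TSV/CSV and listed in the manifest.
#' @return a list with `manifest` (a [RunManifest-class]) and the stage
#'   results: `phenotypes`, `infogain`, `association`, `dendrogram`,
#'   `clusterAccuracy`, `model`, `validation`, `null`.
#' @export
runPipeline <- function(config = PipelineConfig(),
                        simConfig = SimulationConfig(),
                        data = NULL, trait = c("fe", "dmi"),
                        nPerTail = NULL, bootstrap = FALSE,
                        runNull = TRUE, outdir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)$pipeline
  stopifnot(is(config, "PipelineConfig"))
  validObject(config)
  trait <- match.arg(trait)
  seeds <- .stageSeeds(config@rngSeed)
  outputs <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (is.null(data)) {
    simConfig@rngSeed <- seeds[["simulate"]]
    data <- stage("simulate", simulateCohorts(simConfig))
  }
  counts_ref <- data$ref$abundance
  n_features <- nrow(counts_ref)

  filtered <- stage("filter",
                    prevalenceFilter(counts_ref, config@minPrevalence))
  cpm <- stage("normalize", cpmNormalize(filtered))

  phen <- stage("phenotypes", {
    p <- deriveFE(data$ref$phenotypes)
    npt <- if (is.null(nPerTail)) floor(nrow(p) / 2) else as.integer(nPerTail)
    assignGroups(p, trait = trait, nPerTail = npt)
  })

  ig <- stage("infogain", {
    tbl <- infoGainTable(cpm, phen)
    selectTopPercentile(tbl, config@igPercentile)
  })
  selected <- .subsetFeatures(cpm, match(ig$feature_id[ig$selected],
                                         featureIds(cpm)))

  assoc <- stage("metagwas", metaGWAS(selected, phen, alpha = config@alpha))
  sig_ids <- assoc$feature_id[assoc$significant]
  if (length(sig_ids) < 2L)
    stop("pipeline stage 'metagwas' failed: fewer than 2 significant contigs")
  grp <- setNames(as.character(phen$group), phen$animal_id)
  assigned <- intersect(sampleIds(cpm), names(grp)[grp != "unassigned"])
  sig_m <- .subsetFeatures(cpm, match(sig_ids, featureIds(cpm)))[, assigned]

  dend <- stage("cluster", {
    if (bootstrap)
      multiscaleBootstrap(sig_m, scales = config@bootScales,
                          bPerScale = config@nBootReplicates,
                          seed = seeds[["bootstrap"]])
    else hcluster(sig_m)
  })
  acc <- stage("cluster", clusterAccuracy(dend, grp[assigned], k = 2L))

  val_cpm <- stage("normalize",
                   cpmNormalize(prevalenceFilter(data$val$abundance, 1L)))
  yref <- setNames(if (trait == "fe") phen$fe else phen$dmi,
                   phen$animal_id)[sampleIds(sig_m)]
  val_phen <- deriveFE(data$val$phenotypes)
  yval <- setNames(if (trait == "fe") val_phen$fe else val_phen$dmi,
                   val_phen$animal_id)[sampleIds(val_cpm)]

  model <- stage("predict", {
    lam <- selectLambda(sig_m, yref, strategy = config@lambdaStrategy,
                        seed = seeds[["lambda"]],
                        lambda = if (config@lambdaStrategy == "fixed")
                          config@lambdaValue else NULL)
    fitLasso(sig_m, yref, lambda = lam)
  })
  validation <- stage("predict",
                      suppressMessages(predictValidation(model, val_cpm, yval)))

  null <- NULL
  if (runNull)
    null <- stage("null", randomContigNull(
      cpm[, assigned], yref, val_cpm, yval, subsetSize = length(sig_ids),
      nReplicates = config@nNullReplicates, seed = seeds[["null"]],
      lambdaStrategy = config@lambdaStrategy,
      lambdaValue = if (config@lambdaStrategy == "fixed")
        config@lambdaValue else NULL,
      observed = validation$accuracy))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(outdir, f)
    writeAbundanceTable(cpm, out("reference_cpm.tsv"))
    writePhenotypeTable(phen, out("reference_phenotypes.csv"))
    writeInfoGainTable(ig, out("infogain.tsv"))
    write.table(as.data.frame(assoc), out("metagwas.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeDendrogram(dend, newickPath = out("dendrogram.nwk"),
                    edgesPath = out("dendrogram_edges.tsv"))
    writeLassoModel(model, out("lasso_model.tsv"))
    if (!is.null(null))
      write.table(data.frame(accuracy = replicateAccuracies(null)),
                  out("null_accuracies.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    outputs <- c("reference_cpm.tsv", "reference_phenotypes.csv",
                 "infogain.tsv", "metagwas.tsv", "dendrogram.nwk",
                 "dendrogram_edges.tsv", "lasso_model.tsv",
                 if (!is.null(null)) "null_accuracies.tsv")
  }

  manifest <- new("RunManifest",
    config = list(minPrevalence = config@minPrevalence,
                  igPercentile = config@igPercentile, alpha = config@alpha,
                  nNullReplicates = config@nNullReplicates,
                  rngSeed = config@rngSeed,
                  lambdaStrategy = config@lambdaStrategy,
                  trait = trait),
    seeds = seeds,
    counts = c(n_features = n_features,
               after_prevalence = nrow(filtered),
               after_infogain = sum(ig$selected),
               significant = length(sig_ids)),
    outputs = outputs)

  list(manifest = manifest, phenotypes = phen, infogain = ig,
       association = assoc, dendrogram = dend, clusterAccuracy = acc,
       model = model, validation = validation, null = null)
}
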