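#' @include AllClasses.R AllGenerics.R
NULL

#' Simulation settings constructor
#'
#' Defaults emulate the study design the package targets: a reference herd
#' of 30 cows split into two latent feed-efficiency classes of 15, an
#' independent validation herd of 31 cows, 2,000 contigs of which 50 carry
#' a planted HIGH/LOW log-abundance shift of 1.5 within-group SDs, 60% of
#' those effects persisting in the validation population, overdispersed
#' compositional counts, and 85% of reference contigs quantifiable in the
#' validation cohort.
#'
#' @param nRef,nVal reference / validation cohort sizes.
#' @param nContigs number of contig features.
#' @param nInformative number of contigs carrying planted signal.
#' @param effectSize standardized mean shift of log-abundance between the
#'   latent HIGH and LOW classes (difference in units of the within-class
#'   log-abundance SD).
#' @param sharedFraction fraction of planted effects that persist in the
#'   validation population.
#' @param dispersion negative-binomial overdispersion phi (count variance
#'   `mu + phi * mu^2`; gamma shape `1/phi`).
#' @param librarySizeRange min/max total counts per sample.
#' @param mappedFraction fraction of reference contigs present in the
#'   validation abundance matrix.
#' @param feClassMeans,feSd FE phenotype means of the two latent classes
#'   and the within-class SD. The defaults (1.5/1.1, sd 0.156) make an
#'   FE-based 15/15 extreme-group assignment agree with the latent class
#'   for roughly 90% of animals, so group labels are realistically noisy.
#' @param rngSeed integer seed; the whole simulation is reproducible from it.
#' @return a [SimulationConfig-class].
#' @export
SimulationConfig <- function(nRef = 30L, nVal = 31L, nContigs = 2000L,
                             nInformative = 50L, effectSize = 1.5,
                             sharedFraction = 0.6, dispersion = 0.5,
                             librarySizeRange = c(1e5, 3e5),
                             mappedFraction = 0.85,
                             feClassMeans = c(high = 1.5, low = 1.1),
                             feSd = 0.156, rngSeed = 1L) {
  new("SimulationConfig", nRef = as.integer(nRef), nVal = as.integer(nVal),
      nContigs = as.integer(nContigs), nInformative = as.integer(nInformative),
      effectSize = effectSize, sharedFraction = sharedFraction,
      dispersion = dispersion, librarySizeRange = librarySizeRange,
      mappedFraction = mappedFraction, feClassMeans = feClassMeans,
      feSd = feSd, rngSeed = as.integer(rngSeed))
}

# Draw one cohort's count matrix given per-contig baseline log-means and a
# per-contig effect (log-scale shift applied with opposite halves to the two
# latent classes). Counts are multinomial on gamma intensities, so each
# sample's counts sum exactly to its drawn library size while marginal
# contig counts stay negative-binomial-like (overdispersed).
.drawCohort <- function(base_log, effect_log, latent_class, cfg, id_prefix) {
  p <- length(base_log)
  n <- length(latent_class)
  shape <- 1 / cfg@dispersion
  lib <- round(runif(n, cfg@librarySizeRange[1], cfg@librarySizeRange[2]))
  counts <- matrix(0, nrow = p, ncol = n,
                   dimnames = list(names(base_log),
                                   sprintf("%s%02d", id_prefix, seq_len(n))))
  for (i in seq_len(n)) {
    logmu <- base_log + (latent_class[i] - 0.5) * effect_log
    intensity <- rgamma(p, shape = shape, rate = shape / exp(logmu))
    if (sum(intensity) <= 0) intensity <- rep(1, p)
    counts[, i] <- rmultinom(1, size = lib[i], prob = intensity)
  }
  list(counts = counts, library_sizes = lib)
}

.drawPhenotypes <- function(latent_class, cfg, ids, population) {
  n <- length(latent_class)
  fe <- ifelse(latent_class == 1L,
               rnorm(n, cfg@feClassMeans[["high"]], cfg@feSd),
               rnorm(n, cfg@feClassMeans[["low"]], cfg@feSd))
  fe <- pmax(fe, 0.2)
  dmi <- pmax(rnorm(n, 22, 2), 10)
  PhenotypeTable(data.frame(
    animal_id = ids,
    milk_yield = fe * dmi,
    dmi = dmi,
    fat_pct = rnorm(n, 3.8, 0.3),
    protein_pct = rnorm(n, 3.3, 0.2),
    body_weight = pmax(rnorm(n, 650, 40), 400),
    parity = sample(c("primiparous", "multiparous"), n, replace = TRUE),
    population = population,
    stringsAsFactors = FALSE
  ))
}

#' Simulate paired reference and validation cohorts
#'
#' Generates a reference cohort (abundance matrix plus phenotypes) with a
#' planted contig-phenotype signal, and a validation cohort from the same
#' contig universe but with re-drawn baselines (a different diet and
#' environment), where only `sharedFraction` of the planted effects
#' persist and only `mappedFraction` of the contigs are quantifiable.
#'
#' Per contig, baseline log-abundance is drawn once; informative contigs
#' receive a +/- `effectSize`-standardized shift between the two latent
#' classes (half the shift on each side, direction random per contig).
#' Counts are drawn compositionally (multinomial over gamma intensities)
#' so each sample's counts sum exactly to its library size while per-contig
#' counts are overdispersed. FE phenotypes are drawn around latent-class
#' means so that extreme-group assignment on FE matches the latent class
#' about 90% of the time at the defaults; milk yield is `fe * dmi`.
#'
#' @param cfg a [SimulationConfig-class].
#' @return a list with elements `ref` and `val` (each a list with
#'   `abundance`, an [AbundanceMatrix-class] of counts, `phenotypes`, a
#'   [PhenotypeTable-class], and `library_sizes`), and `truth`, a
#'   `DataFrame` of planted contigs (`feature_id`, `sign`, `shared`) whose
#'   `metadata()` carries the latent class of every animal and the FE
#'   phenotype model parameters.
#' @export
simulateCohorts <- function(cfg = SimulationConfig()) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  set.seed(cfg@rngSeed)
  p <- cfg@nContigs
  ids <- sprintf("contig_%05d", seq_len(p))

  base_log <- setNames(rnorm(p, mean = 0, sd = 1.5), ids)
  informative <- sort(sample.int(p, cfg@nInformative))
  signs <- sample(c(-1, 1), cfg@nInformative, replace = TRUE)
  n_shared <- round(cfg@sharedFraction * cfg@nInformative)
  shared <- rep(FALSE, cfg@nInformative)
  if (cfg@nInformative > 0L && n_shared > 0L)
    shared[sample.int(cfg@nInformative, n_shared)] <- TRUE

  # standardized shift: difference between class means in units of the
  # within-class log-abundance SD implied by the gamma intensity noise
  sigma_log <- sqrt(trigamma(1 / cfg@dispersion))
  effect_ref <- numeric(p)
  effect_ref[informative] <- signs * cfg@effectSize * sigma_log

  class_ref <- sample(rep(c(1L, 0L), length.out = cfg@nRef))
  ref_draw <- .drawCohort(base_log, effect_ref, class_ref, cfg, "cowR")
  ref_phen <- .drawPhenotypes(class_ref, cfg,
                              colnames(ref_draw$counts), "reference")

  base_val <- base_log + rnorm(p, 0, 0.3)  # environment/diet shift
  effect_val <- numeric(p)
  effect_val[informative[shared]] <- signs[shared] * cfg@effectSize * sigma_log
  class_val <- sample(rep(c(1L, 0L), length.out = cfg@nVal))
  val_draw <- .drawCohort(base_val, effect_val, class_val, cfg, "cowV")
  val_phen <- .drawPhenotypes(class_val, cfg,
                              colnames(val_draw$counts), "validation")

  mapped <- sort(sample.int(p, round(cfg@mappedFraction * p)))
  val_counts <- val_draw$counts[mapped, , drop = FALSE]

  truth <- DataFrame(feature_id = ids[informative],
                     sign = signs, shared = shared)
  metadata(truth) <- list(
    ref_class = setNames(ifelse(class_ref == 1L, "HIGH", "LOW"),
                         colnames(ref_draw$counts)),
    val_class = setNames(ifelse(class_val == 1L, "HIGH", "LOW"),
                         colnames(val_counts)),
    fe_class_means = cfg@feClassMeans, fe_sd = cfg@feSd,
    effect_log_shift = cfg@effectSize * sigma_log,
    mapped_features = ids[mapped]
  )

  list(
    ref = list(abundance = AbundanceMatrix(ref_draw$counts, unit = "counts"),
               phenotypes = ref_phen,
               library_sizes = ref_draw$library_sizes),
    val = list(abundance = AbundanceMatrix(val_counts, unit = "counts"),
               phenotypes = val_phen,
               library_sizes = val_draw$library_sizes),
    truth = truth
  )
}

#' Text summary of a simulated study
#'
#' @param sim the list returned by [simulateCohorts()].
#' @return character vector of report lines (also printed).
#' @export
summarizeSimulation <- function(sim) {
  ref <- sim$ref; val <- sim$val; truth <- sim$truth
  cls <- metadata(truth)$ref_class
  a_ref <- abundanceValues(ref$abundance)
  a_val <- abundanceValues(val$abundance)
  lines <- c(
    sprintf("Reference animals: %d (HIGH %d / LOW %d by latent class)",
            ncol(a_ref), sum(cls == "HIGH"), sum(cls == "LOW")),
    sprintf("Validation animals: %d", ncol(a_val)),
    sprintf("Contigs: %d reference, %d mapped in validation (%.0f%%)",
            nrow(a_ref), nrow(a_val), 100 * nrow(a_val) / nrow(a_ref)),
    if (nrow(truth) == 0L) "Planted contigs: none (null simulation)"
    else sprintf("Planted contigs: %d (%d shared with validation)",
                 nrow(truth), sum(truth$shared)),
    sprintf("Sparsity: %.1f%% zeros (reference)", 100 * mean(a_ref == 0)),
    sprintf("Library sizes: %s-%s (median %s) reference",
            format(min(ref$library_sizes), big.mark = ","),
            format(max(ref$library_sizes), big.mark = ","),
            format(median(ref$library_sizes), big.mark = ","))
  )
  if (nrow(truth) > 0L) {
    cpm <- sweep(a_ref, 2, colSums(a_ref), "/") * 1e6
    hi <- names(cls)[cls == "HIGH"]; lo <- names(cls)[cls == "LOW"]
    lcpm <- log1p(cpm[truth$feature_id, , drop = FALSE])
    d <- rowMeans(lcpm[, hi, drop = FALSE]) - rowMeans(lcpm[, lo, drop = FALSE])
    s <- apply(lcpm, 1, sd)
    lines <- c(lines, sprintf(
      "Realized |standardized effect| on log1p-CPM: median %.2f",
      median(abs(d) / pmax(s, 1e-12))))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
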