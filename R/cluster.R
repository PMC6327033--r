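#' @include AllClasses.R AllGenerics.R
NULL

# Leaf sets under each internal node of an hclust merge tree, as sorted
# "a|b|c" signatures. Node i of merge corresponds to edge i.
.edgeSignatures <- function(hc) {
  n <- length(hc$labels)
  merge <- hc$merge
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    pick <- function(j) if (j < 0) hc$labels[-j] else sets[[j]]
    sets[[i]] <- c(pick(merge[i, 1]), pick(merge[i, 2]))
  }
  vapply(sets, function(s) paste(sort(s), collapse = "|"), character(1))
}

# Correlation-distance UPGMA over animals (columns). NA correlations (an
# animal constant over the resampled features) are treated as zero
# correlation, i.e. maximal typical distance 1.
.corUpgma <- function(a, onZeroVariance = c("error", "zero")) {
  onZeroVariance <- match.arg(onZeroVariance)
  v <- apply(a, 2, sd)
  if (any(v == 0)) {
    if (onZeroVariance == "error")
      stop("animal(s) with zero-variance abundance profile: ",
           paste(colnames(a)[v == 0], collapse = ", "))
  }
  cc <- suppressWarnings(cor(a))
  cc[is.na(cc)] <- 0
  hclust(as.dist(1 - cc), method = "average")
}

#' Hierarchical clustering of animals on selected contigs
#'
#' Clusters animals by average linkage (UPGMA) on correlation distance
#' `1 - Pearson(profile_i, profile_j)` between their contig-abundance
#' profiles — the default distance/linkage combination of multiscale
#' bootstrap clustering tools. The result is deterministic given the input
#' order; distance ties are resolved by the standard lowest-index merge.
#'
#' @param m an [AbundanceMatrix-class], typically CPM restricted to the
#'   significant metaGWAS contigs; needs >= 3 samples and >= 2 features.
#' @return a [SupportedDendrogram-class] without support values (run
#'   [multiscaleBootstrap()] to add them).
#' @export
hcluster <- function(m) {
  stopifnot(is(m, "AbundanceMatrix"))
  a <- abundanceValues(m)
  if (ncol(a) < 3L) stop("at least 3 samples are required")
  if (nrow(a) < 2L) stop("at least 2 features are required")
  hc <- .corUpgma(a, onZeroVariance = "error")
  sig <- .edgeSignatures(hc)
  edges <- DataFrame(node = seq_along(sig), signature = sig,
                     n_leaves = lengths(strsplit(sig, "|", fixed = TRUE)),
                     height = hc$height)
  new("SupportedDendrogram", hclust = hc, leafIds = hc$labels, edges = edges,
      scales = numeric(), nboot = 0L, seed = NA_integer_)
}

#' @rdname SupportedDendrogram-class
#' @export
setMethod("clusterEdges", "SupportedDendrogram", function(x) x@edges)

setMethod("show", "SupportedDendrogram", function(object) {
  cat(sprintf("SupportedDendrogram: %d animals, UPGMA on correlation distance\n",
              length(object@leafIds)))
  if (length(object@scales))
    cat(sprintf("  multiscale bootstrap: %d replicates x %d scales (%.1f-%.1f)\n",
                object@nboot, length(object@scales),
                min(object@scales), max(object@scales)))
  else cat("  no bootstrap support computed yet\n")
})

#' Multiscale bootstrap support (BP and AU) for every cluster edge
#'
#' For each resampling scale `r`, draws `ceiling(r * p)` of the `p`
#' features with replacement `bPerScale` times, re-clusters the animals,
#' and records per original edge the bootstrap probability `BP_r`: the
#' fraction of replicate dendrograms containing that edge's exact leaf
#' set. The approximately unbiased p-value is then obtained by probit
#' extrapolation across scales: `psi(r) = qnorm(1 - BP_r)` is fitted as
#' `v * sqrt(r) + c / sqrt(r)` by weighted least squares (binomial
#' weights), and `AU = 1 - pnorm(v - c)`. Boundary bootstrap proportions
#' are moved off 0/1 by the continuity correction `(count + 0.5) / (b + 1)`
#' before the probit transform (reported BP values stay uncorrected). An
#' edge present in every replicate at every scale has BP 1 everywhere and
#' AU 1 by definition; an edge never observed has AU 0 and is flagged.
#'
#' Features (contigs) are resampled; animals are what is clustered. The
#' RNG is consumed scale by scale in the order of `scales`, then replicate
#' by replicate, so a run with the same seed whose `scales` vector starts
#' with the same values reproduces the leading scales' resamples exactly.
#'
#' @param m an [AbundanceMatrix-class] (animals in columns).
#' @param scales resampling ratios; default `seq(0.5, 1.4, by = 0.1)`.
#' @param bPerScale bootstrap replicates per scale (>= 100 for a usable
#'   probit fit; default 1000).
#' @param seed integer RNG seed.
#' @return a [SupportedDendrogram-class] whose edge table gains `bp1`
#'   (BP at scale 1), `au`, `fit_rss`, `fit_df` and `flag` columns, with
#'   the per-scale BP matrix in `metadata(clusterEdges(x))$bp_by_scale`.
#' @export
multiscaleBootstrap <- function(m, scales = seq(0.5, 1.4, by = 0.1),
                                bPerScale = 1000L, seed = 1L) {
  stopifnot(length(scales) >= 2L, all(scales > 0), bPerScale >= 100L)
  d <- hcluster(m)
  a <- abundanceValues(m)
  p <- nrow(a)
  orig_sig <- d@edges$signature
  n_edge <- length(orig_sig)

  counts <- matrix(0L, nrow = n_edge, ncol = length(scales))
  set.seed(as.integer(seed))
  for (s in seq_along(scales)) {
    m_r <- as.integer(ceiling(scales[s] * p))
    for (b in seq_len(bPerScale)) {
      idx <- sample.int(p, m_r, replace = TRUE)
      hc_b <- .corUpgma(a[idx, , drop = FALSE], onZeroVariance = "zero")
      counts[, s] <- counts[, s] + (orig_sig %in% .edgeSignatures(hc_b))
    }
  }

  r_actual <- ceiling(scales * p) / p
  bp <- counts / bPerScale
  au <- fit_rss <- rep(NA_real_, n_edge)
  fit_df <- rep(NA_integer_, n_edge)
  flag <- rep(NA_character_, n_edge)
  for (e in seq_len(n_edge)) {
    cnt <- counts[e, ]
    if (all(cnt == bPerScale)) {
      au[e] <- 1; flag[e] <- "always present"; next
    }
    if (all(cnt == 0L)) {
      au[e] <- 0; flag[e] <- "never observed"; next
    }
    pr <- (cnt + 0.5) / (bPerScale + 1)  # continuity correction off 0/1
    z <- qnorm(1 - pr)
    X <- cbind(sqrt(r_actual), 1 / sqrt(r_actual))
    w <- bPerScale * dnorm(z)^2 / (pr * (1 - pr))
    fit <- tryCatch(lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      flag[e] <- "fit failure"; next
    }
    v <- fit$coefficients[1]; cc <- fit$coefficients[2]
    au[e] <- 1 - pnorm(v - cc)
    fit_rss[e] <- sum(w * fit$residuals^2)
    fit_df[e] <- length(scales) - 2L
  }

  i1 <- which.min(abs(scales - 1))
  edges <- d@edges
  edges$bp1 <- if (isTRUE(all.equal(scales[i1], 1))) bp[, i1] else NA_real_
  edges$au <- au
  edges$fit_rss <- fit_rss
  edges$fit_df <- fit_df
  edges$flag <- flag
  dimnames(bp) <- list(orig_sig, paste0("r", format(r_actual, digits = 3)))
  metadata(edges)$bp_by_scale <- bp
  metadata(edges)$scales <- r_actual

  initialize(d, edges = edges, scales = r_actual,
             nboot = as.integer(bPerScale), seed = as.integer(seed))
}

#' Classification accuracy of a dendrogram cut against known groups
#'
#' Cuts the tree into `k` clusters and scores the best concordant fraction
#' over all assignments of clusters to truth labels.
#'
#' @param d a [SupportedDendrogram-class].
#' @param truth named vector of labels (names are animal ids), or an
#'   unnamed vector aligned with the dendrogram's leaves.
#' @param k number of clusters (default 2).
#' @return a [ClusterAccuracyReport-class].
#' @export
clusterAccuracy <- function(d, truth, k = 2L) {
  stopifnot(is(d, "SupportedDendrogram"))
  k <- as.integer(k)
  leaves <- d@leafIds
  if (k > length(leaves)) stop("k exceeds the number of leaves")
  if (!is.null(names(truth))) {
    if (!all(leaves %in% names(truth)))
      stop("every leaf needs a truth label")
    truth <- truth[leaves]
  } else stopifnot(length(truth) == length(leaves))
  truth <- as.character(truth)
  cl <- cutree(d@hclust, k = k)[leaves]

  labs <- unique(truth)
  perms <- .permutations(labs)
  best <- 0
  for (pm in perms) {
    mapping <- setNames(rep(pm, length.out = k), seq_len(k))
    best <- max(best, mean(mapping[as.character(cl)] == truth))
  }
  new("ClusterAccuracyReport", k = k, predicted = cl, labels = truth,
      accuracy = best, table = table(cluster = cl, label = truth))
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(.permutations(x[-i]), function(p) c(x[i], p)))
  out
}

setMethod("show", "ClusterAccuracyReport", function(object) {
  cat(sprintf("ClusterAccuracyReport: k = %d, accuracy = %.3f\n",
              object@k, object@accuracy))
  print(object@table)
})

#' Nested intake clustering within feed-efficiency groups
#'
#' Within each outer feed-efficiency group (HIGH/LOW from the phenotype
#' table's `group` column), splits the animals into high/low halves of an
#' inner trait (default DMI), clusters the subgroup on the contigs
#' significant in the inner trait's metaGWAS, and reports support and
#' two-cluster accuracy per subgroup with composite labels such as
#' `"H-Hdmi"`. Subgroups smaller than 3 animals are skipped with a warning.
#'
#' @param m an [AbundanceMatrix-class] over the grouped animals.
#' @param phen a [PhenotypeTable-class] with a `group` column (outer FE
#'   groups).
#' @param assocInner metaGWAS `DataFrame` for the inner trait, used to
#'   pick the contigs (its `significant` features).
#' @param innerTrait inner trait column (default `"dmi"`).
#' @param bootstrap run [multiscaleBootstrap()] per subgroup.
#' @param bPerScale,seed bootstrap settings when `bootstrap = TRUE`.
#' @return a named list (`"HIGH"`, `"LOW"`) of lists with elements
#'   `dendrogram`, `accuracy` (a [ClusterAccuracyReport-class]), and
#'   `labels` (composite class per animal); skipped subgroups are `NULL`.
#' @export
nestedGroupClustering <- function(m, phen, assocInner, innerTrait = "dmi",
                                  bootstrap = FALSE, bPerScale = 1000L,
                                  seed = 1L) {
  stopifnot(is(m, "AbundanceMatrix"), is(phen, "PhenotypeTable"))
  if (!("group" %in% colnames(phen)))
    stop("phenotype table needs a 'group' column (outer FE groups)")
  sel <- assocInner$feature_id[assocInner$significant]
  if (length(sel) < 2L)
    stop("fewer than 2 significant contigs for the inner trait")
  out <- list()
  for (og in c("HIGH", "LOW")) {
    animals <- phen$animal_id[phen$group == og]
    animals <- intersect(animals, sampleIds(m))
    if (length(animals) < 3L) {
      warning("outer group ", og, " has fewer than 3 animals; skipped")
      out[[og]] <- NULL
      next
    }
    ph_sub <- phen[match(animals, phen$animal_id), ]
    inner <- assignGroups(ph_sub, trait = innerTrait,
                          nPerTail = floor(length(animals) / 2))
    inner_lab <- setNames(inner$group, inner$animal_id)
    assigned <- names(inner_lab)[inner_lab != "unassigned"]
    if (length(assigned) < 3L) {
      warning("outer group ", og, " leaves fewer than 3 ", innerTrait,
              "-assigned animals; skipped")
      out[[og]] <- NULL
      next
    }
    sub <- .subsetFeatures(m, match(sel, featureIds(m)))[, assigned]
    dend <- if (bootstrap)
      multiscaleBootstrap(sub, bPerScale = bPerScale, seed = seed)
    else hcluster(sub)
    acc <- clusterAccuracy(dend, inner_lab[assigned], k = 2L)
    composite <- sprintf("%s-%s%s", substr(og, 1, 1),
                         substr(inner_lab, 1, 1), tolower(innerTrait))
    names(composite) <- names(inner_lab)
    out[[og]] <- list(dendrogram = dend, accuracy = acc, labels = composite)
  }
  out
}

#' Principal-component scores of animals
#'
#' Column-centers the sample-by-feature matrix and returns the first two
#' singular-value-decomposition scores per animal. The sign of each
#' component is fixed so that its largest-magnitude feature loading is
#' positive.
#'
#' @param m an [AbundanceMatrix-class] with >= 3 samples.
#' @param nComp number of components (default 2).
#' @return a numeric matrix (animals by components) with the explained
#'   variance fractions as attribute `"var_explained"`.
#' @export
pcaScores <- function(m, nComp = 2L) {
  stopifnot(is(m, "AbundanceMatrix"))
  X <- t(abundanceValues(m))
  if (nrow(X) < 3L) stop("at least 3 animals are required")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  nComp <- min(nComp, length(sv$d))
  flip <- vapply(seq_len(nComp), function(j) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(nComp), drop = FALSE] %*%
                    diag(sv$d[seq_len(nComp)], nComp), 2, flip, "*")
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(nComp)))
  attr(scores, "var_explained") <- (sv$d^2 / sum(sv$d^2))[seq_len(nComp)]
  scores
}

#' Serialize a supported dendrogram
#'
#' Writes the tree as Newick with `au`/`bp` support in node comment blocks
#' (via [ape::write.tree()]), and the flat edge table as TSV.
#'
#' @param d a [SupportedDendrogram-class].
#' @param newickPath,edgesPath output paths (either may be `NULL`).
#' @export
writeDendrogram <- function(d, newickPath = NULL, edgesPath = NULL) {
  stopifnot(is(d, "SupportedDendrogram"))
  if (!is.null(newickPath)) {
    phy <- ape::as.phylo(d@hclust)
    if ("au" %in% colnames(d@edges)) {
      # hclust node i maps to phylo internal node in merge order via
      # matching leaf sets
      sig_phy <- vapply(seq_len(phy$Nnode), function(i) {
        tips <- ape::extract.clade(phy, length(phy$tip.label) + i)$tip.label
        paste(sort(tips), collapse = "|")
      }, character(1))
      idx <- match(sig_phy, d@edges$signature)
      phy$node.label <- sprintf("[au=%.3f,bp=%.3f]",
                                d@edges$au[idx], d@edges$bp1[idx])
    }
    ape::write.tree(phy, file = newickPath)
  }
  if (!is.null(edgesPath)) {
    tab <- as.data.frame(d@edges)
    write.table(tab, edgesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(d)
}
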