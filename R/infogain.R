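#' @include AllClasses.R AllGenerics.R
NULL

#' Euler-Mascheroni constant used as the default entropy scale
#' @keywords internal
.EULER_GAMMA <- 0.57721566490153286

#' Gaussian entropy of a group's abundance distribution, in bits
#'
#' Returns `log2(sd * sqrt(2 * pi * constant))`: the entropy of a Gaussian
#' abundance distribution with the given standard deviation, measured in
#' bits. The multiplicative constant only shifts the entropy by a fixed
#' number of bits and cancels exactly in any entropy difference, so
#' information gain does not depend on it; the default is the
#' Euler-Mascheroni constant (0.5772...). A zero SD yields `-Inf` (a
#' degenerate, perfectly concentrated distribution); callers flag it.
#'
#' @param sd standard deviation(s), >= 0.
#' @param constant positive entropy scale constant.
#' @return entropy in bits (vectorized over `sd`).
#' @export
gaussianEntropy <- function(sd, constant = .EULER_GAMMA) {
  if (any(sd < 0)) stop("sd must be non-negative")
  stopifnot(constant > 0)
  log2(sd * sqrt(2 * pi * constant))
}

# Maximum-likelihood (divide-by-N) standard deviation; guarantees the
# pooled-vs-within variance decomposition that makes information gain >= 0.
.mlSd <- function(x) sqrt(mean((x - mean(x))^2))

#' Information gain of a contig's abundance given HIGH/LOW groups
#'
#' The entropy reduction, in bits, obtained by splitting a contig's CPM
#' values by phenotype group:
#' `IG = H(pooled SD) - (nH * H(sd_HIGH) + nL * H(sd_LOW)) / (nH + nL)`
#' with maximum-likelihood SDs. With ML SDs the pooled variance dominates
#' the weighted within-group variances, so IG is always >= 0; it is
#' invariant to the entropy constant and to rescaling of the abundances.
#' A zero within-group SD means the contig separates a group perfectly and
#' yields `+Inf` (flagged degenerate downstream); a zero pooled SD (a
#' constant contig) yields 0.
#'
#' @param x numeric vector of abundances over grouped samples.
#' @param labels vector of group labels aligned with `x`, with exactly two
#'   levels (e.g. `"HIGH"`/`"LOW"`), each with at least 2 samples.
#' @param constant entropy scale constant (cancels; exposed for the
#'   invariance property only).
#' @return information gain in bits.
#' @examples
#' informationGain(c(1, 2, 3, 4), c("H", "H", "L", "L"))
#' # log2(sqrt(1.25) / 0.5) = 1.1609...
#' @export
informationGain <- function(x, labels, constant = .EULER_GAMMA) {
  stopifnot(length(x) == length(labels))
  lev <- unique(labels)
  if (length(lev) != 2L) stop("labels must have exactly two levels")
  n1 <- sum(labels == lev[1]); n2 <- sum(labels == lev[2])
  if (n1 < 2L || n2 < 2L) stop("both groups need at least 2 samples")
  sd_pool <- .mlSd(x)
  if (sd_pool == 0) return(0)
  sd1 <- .mlSd(x[labels == lev[1]])
  sd2 <- .mlSd(x[labels == lev[2]])
  if (sd1 == 0 || sd2 == 0) return(Inf)
  gaussianEntropy(sd_pool, constant) -
    (n1 * gaussianEntropy(sd1, constant) +
     n2 * gaussianEntropy(sd2, constant)) / (n1 + n2)
}

#' Per-contig information-gain table
#'
#' Computes pooled and within-group maximum-likelihood SDs and the
#' information gain in bits for every feature of a grouped abundance
#' matrix, ranks features by decreasing gain, and (optionally, via
#' [selectTopPercentile()]) flags the top percentile for the metaGWAS.
#'
#' Degenerate features are kept, not dropped: a zero within-group SD
#' separates the groups perfectly and is maximal information (`ig_bits =
#' Inf`, ranked first); a zero pooled SD is a constant feature
#' (`ig_bits = 0`). Both are marked in the `degenerate` column. Ranks use
#' `ties.method = "first"` (stable input order), so they are a permutation
#' of `1..n`.
#'
#' @param m an [AbundanceMatrix-class] (typically CPM) over grouped samples.
#' @param groups vector of `"HIGH"`/`"LOW"` labels aligned with the
#'   samples, or a [PhenotypeTable-class] with a `group` column (animals
#'   matched by id; unassigned animals are excluded).
#' @param constant entropy scale constant (cancels in the gain).
#' @return a `DataFrame` with columns `feature_id`, `n_high`, `n_low`,
#'   `pooled_sd`, `sd_high`, `sd_low`, `ig_bits`, `degenerate`, `rank`,
#'   `selected` (all `FALSE` until [selectTopPercentile()] is applied).
#' @export
infoGainTable <- function(m, groups, constant = .EULER_GAMMA) {
  stopifnot(is(m, "AbundanceMatrix"))
  a <- abundanceValues(m)
  groups <- .resolveGroups(groups, colnames(a))
  a <- a[, !is.na(groups), drop = FALSE]
  groups <- groups[!is.na(groups)]
  hi <- groups == "HIGH"; lo <- groups == "LOW"
  n_high <- sum(hi); n_low <- sum(lo)
  if (n_high < 2L || n_low < 2L)
    stop("both groups need at least 2 samples")

  ml_sd_rows <- function(x) {
    mu <- rowMeans(x)
    sqrt(rowMeans((x - mu)^2))
  }
  sd_pool <- ml_sd_rows(a)
  sd_high <- ml_sd_rows(a[, hi, drop = FALSE])
  sd_low <- ml_sd_rows(a[, lo, drop = FALSE])

  ig <- gaussianEntropy(pmax(sd_pool, .Machine$double.xmin), constant) -
    (n_high * gaussianEntropy(pmax(sd_high, .Machine$double.xmin), constant) +
     n_low * gaussianEntropy(pmax(sd_low, .Machine$double.xmin), constant)) /
    (n_high + n_low)
  degenerate <- sd_pool == 0 | sd_high == 0 | sd_low == 0
  ig[sd_high == 0 | sd_low == 0] <- Inf
  ig[sd_pool == 0] <- 0

  tbl <- DataFrame(
    feature_id = rownames(a),
    n_high = n_high, n_low = n_low,
    pooled_sd = unname(sd_pool), sd_high = unname(sd_high),
    sd_low = unname(sd_low),
    ig_bits = unname(ig), degenerate = unname(degenerate),
    rank = unname(rank(-ig, ties.method = "first")),
    selected = FALSE
  )
  metadata(tbl)$constant <- constant
  tbl
}

# groups may be a plain label vector or a PhenotypeTable; returns a vector
# aligned with sample ids, NA for unassigned animals.
.resolveGroups <- function(groups, sample_ids) {
  if (is(groups, "PhenotypeTable")) {
    if (!("group" %in% colnames(groups)))
      stop("phenotype table has no 'group' column; run assignGroups() first")
    g <- setNames(as.character(groups$group), groups$animal_id)[sample_ids]
  } else {
    stopifnot(length(groups) == length(sample_ids))
    g <- as.character(groups)
  }
  g[!(g %in% c("HIGH", "LOW"))] <- NA_character_
  g
}

#' Select the top information-gain percentile
#'
#' Marks as selected the `ceiling((1 - percentile/100) * n)` top-ranked
#' features — e.g. percentile 95 over 175,969 features selects 8,799.
#' Degenerate infinite-gain features rank first and are therefore always
#' selected. A tie in gain straddling the selection boundary is resolved
#' by stable feature order with a warning.
#'
#' @param tbl a `DataFrame` from [infoGainTable()].
#' @param percentile selection percentile in (0, 100); default 95 keeps
#'   the top 5%.
#' @return the table with the `selected` column set.
#' @export
selectTopPercentile <- function(tbl, percentile = 95) {
  if (nrow(tbl) == 0L) stop("empty information-gain table")
  stopifnot(percentile > 0, percentile < 100)
  n <- nrow(tbl)
  # (100 - percentile) first: 1 - p/100 is inexact in binary and a ulp of
  # excess would inflate the ceiling (e.g. 5% of 100 features -> 6)
  n_keep <- as.integer(ceiling((100 - percentile) * n / 100))
  tbl$selected <- tbl$rank <= n_keep
  if (n_keep < n) {
    ig_sorted <- tbl$ig_bits[order(tbl$rank)]
    if (is.finite(ig_sorted[n_keep]) && ig_sorted[n_keep] == ig_sorted[n_keep + 1L])
      warning("information-gain tie at the selection boundary; ",
              "resolved by stable feature order")
  }
  metadata(tbl)$percentile <- percentile
  metadata(tbl)$n_selected <- n_keep
  tbl
}

#' Write an information-gain table as TSV
#'
#' @param tbl a `DataFrame` from [infoGainTable()].
#' @param path output file path.
#' @export
writeInfoGainTable <- function(tbl, path) {
  write.table(as.data.frame(tbl), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
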