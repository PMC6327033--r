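#' @include AllClasses.R AllGenerics.R
NULL

#' Per-contig logistic metaGWAS
#'
#' Fits, for every feature, a logistic regression of the phenotype group
#' (HIGH coded 1, LOW coded 0) on the feature's CPM abundance
#' (z-standardized by default for numerical stability; the Wald test is
#' invariant to affine rescaling of the predictor) and reports the Wald
#' test on the slope. Features whose abundance completely separates the
#' two groups are flagged: their maximum-likelihood slope diverges, so no
#' p-value is reported and the reason is recorded instead. Constant
#' features are likewise reported as missing-with-reason.
#'
#' @param m an [AbundanceMatrix-class] (typically CPM restricted to
#'   information-gain pre-selected features) over grouped samples.
#' @param groups `"HIGH"`/`"LOW"` labels aligned with the samples, or a
#'   [PhenotypeTable-class] with a `group` column.
#' @param alpha significance level for the `significant` flag (raw
#'   per-test threshold, no multiplicity correction by default).
#' @param standardize z-standardize the predictor before fitting
#'   (recorded in the result; p-values are unaffected).
#' @param p_adjust optional multiple-testing correction method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); when given, the `significant` flag
#'   uses the adjusted p-values.
#' @return a `DataFrame` with columns `feature_id`, `beta` (log-odds per
#'   predictor unit), `se`, `statistic` (Wald z), `p_value`, `converged`,
#'   `separation`, `significant`, `reason`; `metadata()` records `alpha`
#'   and the standardization flag.
#' @export
metaGWAS <- function(m, groups, alpha = 0.05, standardize = TRUE,
                     p_adjust = NULL) {
  stopifnot(is(m, "AbundanceMatrix"), alpha > 0, alpha <= 1)
  a <- abundanceValues(m)
  groups <- .resolveGroups(groups, colnames(a))
  a <- a[, !is.na(groups), drop = FALSE]
  groups <- groups[!is.na(groups)]
  if (length(unique(groups)) < 2L)
    stop("both HIGH and LOW groups must be present")
  if (min(table(groups)) < 2L)
    stop("each group needs at least 2 samples")
  y <- as.integer(groups == "HIGH")

  n_feat <- nrow(a)
  beta <- se <- zstat <- pval <- rep(NA_real_, n_feat)
  converged <- rep(FALSE, n_feat)
  separation <- rep(FALSE, n_feat)
  reason <- rep(NA_character_, n_feat)

  for (k in seq_len(n_feat)) {
    x <- a[k, ]
    s <- sd(x)
    if (s == 0) { reason[k] <- "constant"; next }
    if (standardize) x <- (x - mean(x)) / s
    # complete separation: the predictor's group ranges do not overlap
    if (max(x[y == 0L]) < min(x[y == 1L]) || max(x[y == 1L]) < min(x[y == 0L])) {
      separation[k] <- TRUE
      reason[k] <- "separation"
      next
    }
    quasi <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ x, family = binomial(),
          control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          quasi <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (quasi) {
      # quasi-separation: the Wald SE diverges (Hauck-Donner), so no
      # trustworthy p-value exists; flag alongside complete separation
      separation[k] <- TRUE
      reason[k] <- "quasi-separation"
      next
    }
    cf <- summary(fit)$coefficients
    if (nrow(cf) < 2L) { reason[k] <- "degenerate fit"; next }
    beta[k] <- cf["x", "Estimate"]
    se[k] <- cf["x", "Std. Error"]
    zstat[k] <- cf["x", "z value"]
    pval[k] <- cf["x", "Pr(>|z|)"]
    converged[k] <- isTRUE(fit$converged)
    if (!converged[k]) reason[k] <- "non-convergence"
  }

  p_used <- pval
  if (!is.null(p_adjust)) p_used <- p.adjust(pval, method = p_adjust)
  tbl <- DataFrame(
    feature_id = rownames(a),
    beta = beta, se = se, statistic = zstat, p_value = pval,
    converged = converged, separation = separation,
    significant = !is.na(p_used) & p_used < alpha & converged & !separation,
    reason = reason
  )
  metadata(tbl) <- list(alpha = alpha, standardized = standardize,
                        p_adjust = p_adjust,
                        n_high = sum(y == 1L), n_low = sum(y == 0L))
  tbl
}

#' Taxonomy-level association with group and parity fixed effects
#'
#' Associates taxon relative abundances with the feed-efficiency group,
#' adjusting for parity. The default direction regresses each taxon's
#' relative abundance on `group + parity` with a logit link
#' (quasi-binomial, appropriate for proportions) and reports the
#' group-effect p-value; the alternative direction treats the group as
#' the binary response and the abundance as the predictor.
#'
#' @param rel an [AbundanceMatrix-class] with unit `"relative"`.
#' @param groups `"HIGH"`/`"LOW"` labels or a [PhenotypeTable-class].
#' @param parity `"primiparous"`/`"multiparous"` per sample, or taken from
#'   the phenotype table when `groups` is one.
#' @param alpha significance level.
#' @param direction `"abundance"` (abundance as response, default) or
#'   `"group"` (group as response).
#' @return a `DataFrame` with one row per taxon: `feature_id`, `beta`
#'   (HIGH-vs-LOW group effect), `se`, `statistic`, `p_value`,
#'   `significant`, `reason`.
#' @export
taxaAssociation <- function(rel, groups, parity = NULL, alpha = 0.05,
                            direction = c("abundance", "group")) {
  stopifnot(is(rel, "AbundanceMatrix"))
  direction <- match.arg(direction)
  a <- abundanceValues(rel)
  if (any(a < 0) || any(a > 1))
    stop("taxaAssociation() expects relative abundances in [0, 1]")
  if (is.null(parity)) {
    if (!is(groups, "PhenotypeTable"))
      stop("parity must be given unless groups is a PhenotypeTable")
    parity <- setNames(as.character(groups$parity),
                       groups$animal_id)[colnames(a)]
  }
  groups <- .resolveGroups(groups, colnames(a))
  keep <- !is.na(groups) & !is.na(parity)
  a <- a[, keep, drop = FALSE]
  g <- factor(groups[keep], levels = c("LOW", "HIGH"))
  par_f <- factor(parity[keep], levels = c("primiparous", "multiparous"))
  if (nlevels(droplevels(par_f)) > 1L &&
      all(table(g, droplevels(par_f)) %in% c(0L, table(g)))) {
    warning("parity is fully confounded with group: rank-deficient design")
  }

  n_feat <- nrow(a)
  beta <- se <- stat <- pval <- rep(NA_real_, n_feat)
  reason <- rep(NA_character_, n_feat)
  for (k in seq_len(n_feat)) {
    x <- a[k, ]
    if (all(x == 0)) { reason[k] <- "absent in all samples"; next }
    if (sd(x) == 0) {
      # no abundance variation: no group effect is estimable beyond noise
      beta[k] <- 0; pval[k] <- 1; reason[k] <- "constant"
      next
    }
    cf <- if (direction == "abundance") {
      fit <- suppressWarnings(glm(x ~ g + par_f, family = quasibinomial()))
      summary(fit)$coefficients
    } else {
      fit <- suppressWarnings(glm(g ~ x + par_f, family = binomial()))
      summary(fit)$coefficients
    }
    term <- if (direction == "abundance") "gHIGH" else "x"
    if (!(term %in% rownames(cf))) { reason[k] <- "rank-deficient"; next }
    beta[k] <- cf[term, 1]; se[k] <- cf[term, 2]
    stat[k] <- cf[term, 3]; pval[k] <- cf[term, 4]
  }
  tbl <- DataFrame(feature_id = rownames(a), beta = beta, se = se,
                   statistic = stat, p_value = pval,
                   significant = !is.na(pval) & pval < alpha,
                   reason = reason)
  metadata(tbl) <- list(alpha = alpha, direction = direction)
  tbl
}

#' Spearman correlations of top-associated contigs with production traits
#'
#' Takes the `top_k` features with the smallest metaGWAS p-values and
#' computes their Spearman rank correlation against each continuous
#' feed-efficiency-related trait. Milk solids are derived as
#' `milk_yield * (fat_pct + protein_pct) / 100` when the component traits
#' are available.
#'
#' @param m an [AbundanceMatrix-class] over the phenotyped samples.
#' @param phen a [PhenotypeTable-class] (animals matched to samples by id).
#' @param assoc the metaGWAS `DataFrame` used for the top-k ranking.
#' @param top_k number of smallest-p features to correlate (default 100).
#' @param traits trait columns to correlate against.
#' @return a `DataFrame` of features by traits holding Spearman rho;
#'   `metadata()$summary` holds per-trait mean absolute rho and quartiles.
#' @export
traitCorrelations <- function(m, phen, assoc, top_k = 100,
                              traits = c("fe", "rfi", "dmi", "milk_yield",
                                         "milk_solids", "body_weight")) {
  stopifnot(is(m, "AbundanceMatrix"), is(phen, "PhenotypeTable"))
  a <- abundanceValues(m)
  idx <- match(colnames(a), phen$animal_id)
  if (anyNA(idx)) stop("samples missing from the phenotype table: ",
                       paste(colnames(a)[is.na(idx)], collapse = ", "))
  ph <- phen[idx, ]
  if (!("milk_solids" %in% colnames(ph)) &&
      all(c("fat_pct", "protein_pct") %in% colnames(ph)))
    ph <- .setPhenoCol(ph, "milk_solids",
                       ph$milk_yield * (ph$fat_pct + ph$protein_pct) / 100)
  traits <- intersect(traits, colnames(ph))
  if (!length(traits)) stop("none of the requested traits are present")

  ok <- !is.na(assoc$p_value)
  if (sum(ok) < top_k)
    stop("top_k (", top_k, ") exceeds the number of features with a p-value (",
         sum(ok), ")")
  sel <- assoc$feature_id[ok][order(assoc$p_value[ok])][seq_len(top_k)]
  xs <- t(a[sel, , drop = FALSE])

  rho <- matrix(NA_real_, nrow = top_k, ncol = length(traits),
                dimnames = list(sel, traits))
  for (tr in traits) {
    v <- as.numeric(ph[[tr]])
    if (sd(v) == 0) next  # zero-variance trait: rho undefined, left NA
    rho[, tr] <- suppressWarnings(
      apply(xs, 2, function(col)
        if (sd(col) == 0) NA_real_ else cor(col, v, method = "spearman")))
  }
  out <- DataFrame(feature_id = sel, as.data.frame(rho, check.names = FALSE))
  summ <- do.call(rbind, lapply(traits, function(tr) {
    r <- rho[, tr]
    data.frame(trait = tr, mean_abs_rho = mean(abs(r), na.rm = TRUE),
               q1 = quantile(r, 0.25, na.rm = TRUE, names = FALSE),
               median = quantile(r, 0.5, na.rm = TRUE, names = FALSE),
               q3 = quantile(r, 0.75, na.rm = TRUE, names = FALSE))
  }))
  metadata(out) <- list(summary = summ, top_k = top_k)
  out
}
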