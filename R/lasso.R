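#' @include AllClasses.R AllGenerics.R
NULL

# Internal: resolve an AbundanceMatrix or plain matrix into an
# animals-by-features numeric matrix.
.predictorMatrix <- function(X) {
  if (is(X, "AbundanceMatrix")) t(abundanceValues(X)) else as.matrix(X)
}

#' L1-penalized linear model by cyclic coordinate descent
#'
#' Minimizes `0.5 * ||y - y0 - X beta||^2 + n * lambda * ||beta||_1`
#' (with `n` the training size, so `lambda` is on a per-observation
#' scale). The intercept `y0` is handled by centering and never
#' penalized. Features are z-standardized by default; `lambda` then acts
#' on the standardized scale (recorded in the model) and coefficients are
#' mapped back to the original CPM scale. Coordinate updates soft-threshold
#' the partial residual correlation; convergence is declared when no
#' coefficient moves by more than `tol` in a full sweep.
#'
#' At `lambda >= max(|X_s' (y - ybar)|) / n` (see [lambdaMax()]) the
#' solution is exactly the all-zero model and predictions collapse to the
#' training mean.
#'
#' @param X training predictors: an [AbundanceMatrix-class] or an
#'   animals-by-features matrix with feature column names.
#' @param y numeric phenotype vector (no missing values).
#' @param lambda penalty, > 0.
#' @param standardize z-standardize features before fitting.
#' @param intercept fit an (unpenalized) intercept by centering.
#' @param tol convergence tolerance on the largest coefficient change.
#' @param maxit maximum coordinate-descent sweeps.
#' @return a [LassoModel-class].
#' @export
fitLasso <- function(X, y, lambda, standardize = TRUE, intercept = TRUE,
                     tol = 1e-8, maxit = 100000L) {
  X <- .predictorMatrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < 3L) stop("at least 3 training animals are required")
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in the training data")
  if (length(lambda) != 1L || !is.finite(lambda) || lambda <= 0)
    stop("lambda must be a single value > 0")
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("feature_%d", seq_len(ncol(X)))

  n <- nrow(X)
  ybar <- if (intercept) mean(y) else 0
  yc <- y - ybar
  ctr <- if (intercept) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2, ctr, "-")
  scl <- rep(1, ncol(X))
  if (standardize) {
    scl <- sqrt(colMeans(Xc^2))
    ok <- scl > 0
    scl[!ok] <- 1  # constant feature: left unscaled, coefficient stays 0
    Xc <- sweep(Xc, 2, scl, "/")
    if (any(!ok)) Xc[, !ok] <- 0
  }

  fit <- .cd_lasso(Xc, yc, lambda, rep(0, ncol(X)), tol, as.integer(maxit))
  if (!fit$converged)
    warning("coordinate descent did not converge in ", maxit, " sweeps")
  beta_std <- fit$beta
  beta <- beta_std / scl
  names(beta) <- colnames(X)
  nz <- beta != 0
  intercept_val <- ybar - sum(ctr[nz] * beta[nz])
  resid <- yc - as.numeric(Xc %*% beta_std)

  new("LassoModel",
      intercept = intercept_val,
      coefficients = beta[nz],
      lambda = lambda, nTrain = n, featureIds = colnames(X),
      center = ctr, scale = scl, standardized = standardize,
      residualSd = sqrt(mean(resid^2)))
}

#' Smallest penalty with an all-zero LASSO solution
#'
#' @inheritParams fitLasso
#' @return `max(|X' (y - ybar)|) / n` on the (standardized, centered)
#'   working scale.
#' @export
lambdaMax <- function(X, y, standardize = TRUE, intercept = TRUE) {
  X <- .predictorMatrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  yc <- if (intercept) y - mean(y) else y
  Xc <- if (intercept) sweep(X, 2, colMeans(X), "-") else X
  if (standardize) {
    scl <- sqrt(colMeans(Xc^2))
    scl[scl == 0] <- Inf
    Xc <- sweep(Xc, 2, scl, "/")
  }
  max(abs(crossprod(Xc, yc))) / n
}

# Warm-started path fit on a pre-standardized working matrix; internal.
.lassoPath <- function(Xs, yc, lambdas, tol = 1e-7, maxit = 100000L) {
  p <- ncol(Xs)
  betas <- matrix(0, nrow = p, ncol = length(lambdas))
  b <- rep(0, p)
  for (i in seq_along(lambdas)) {
    b <- .cd_lasso(Xs, yc, lambdas[i], b, tol, as.integer(maxit))$beta
    betas[, i] <- b
  }
  betas
}

#' Choose the LASSO penalty
#'
#' With `strategy = "cv"`, evaluates a log-spaced grid from `lambdaMax`
#' down four decades by k-fold cross-validation (fold assignment from the
#' current RNG, or from `seed` when given) and returns the penalty with
#' the smallest mean out-of-fold squared error. With `strategy = "fixed"`
#' the configured `lambda` is passed through.
#'
#' @inheritParams fitLasso
#' @param strategy `"cv"` or `"fixed"`.
#' @param folds number of folds (default 5).
#' @param seed optional integer seed for the fold assignment.
#' @param lambda the value returned when `strategy = "fixed"`.
#' @param nLambda grid size (default 50).
#' @return the chosen penalty (with the CV error curve as attribute
#'   `"cv_error"` when cross-validated).
#' @export
selectLambda <- function(X, y, strategy = c("cv", "fixed"), folds = 5L,
                         seed = NULL, lambda = NULL, nLambda = 50L,
                         standardize = TRUE, intercept = TRUE) {
  strategy <- match.arg(strategy)
  if (strategy == "fixed") {
    if (is.null(lambda) || lambda <= 0)
      stop("strategy 'fixed' requires lambda > 0")
    return(lambda)
  }
  X <- .predictorMatrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  folds <- as.integer(folds)
  if (folds > n) stop("more folds than animals")
  if (!is.null(seed)) set.seed(as.integer(seed))
  fold_id <- sample(rep(seq_len(folds), length.out = n))

  lmax <- lambdaMax(X, y, standardize = standardize, intercept = intercept)
  if (lmax <= 0) lmax <- 1e-3
  # descend four decades when n > p; with p >= n the near-zero end of the
  # path is ill-posed (interpolating fits), so stop at 1% of lambda_max
  min_ratio <- if (n > ncol(X)) 1e-4 else 1e-2
  grid <- exp(seq(log(lmax), log(lmax * min_ratio), length.out = nLambda))

  mse <- matrix(NA_real_, nrow = folds, ncol = nLambda)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    ctr <- if (intercept) colMeans(Xtr) else rep(0, ncol(X))
    Xc <- sweep(Xtr, 2, ctr, "-")
    scl <- rep(1, ncol(X))
    if (standardize) {
      scl <- sqrt(colMeans(Xc^2)); scl[scl == 0] <- 1
      Xc <- sweep(Xc, 2, scl, "/")
    }
    ybar <- if (intercept) mean(ytr) else 0
    betas <- .lassoPath(Xc, ytr - ybar, grid)
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, ctr, "-"), 2, scl, "/")
    pred <- Xte %*% betas + ybar
    mse[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cv_err <- colMeans(mse)
  out <- grid[which.min(cv_err)]
  attr(out, "cv_error") <- data.frame(lambda = grid, mse = cv_err)
  out
}

#' Predict phenotypes in a validation population
#'
#' Applies a trained [LassoModel-class] to validation-animal CPM:
#' `yhat = y0 + x* beta`. Validation features are matched to training
#' features by contig id; features absent from the validation matrix are
#' imputed as 0 CPM and their count is reported (cross-population mapping
#' is rarely complete). Predictive accuracy is the Pearson correlation
#' between predicted and observed phenotypes.
#'
#' @param model a [LassoModel-class].
#' @param Xval validation predictors ([AbundanceMatrix-class] or matrix).
#' @param yval observed validation phenotypes.
#' @return a list with `accuracy` (Pearson r, `NA` with a `reason` when
#'   the predictions have zero variance), `predictions` (named numeric),
#'   and `n_unmatched` (training features absent from the validation set).
#' @export
predictValidation <- function(model, Xval, yval) {
  stopifnot(is(model, "LassoModel"))
  Xval <- .predictorMatrix(Xval)
  yval <- as.numeric(yval)
  stopifnot(nrow(Xval) == length(yval))
  active <- names(model@coefficients)
  idx <- match(active, colnames(Xval))
  n_unmatched <- sum(is.na(idx))
  Xa <- matrix(0, nrow = nrow(Xval), ncol = length(active))
  if (length(active))
    Xa[, !is.na(idx)] <- Xval[, idx[!is.na(idx)], drop = FALSE]
  pred <- as.numeric(model@intercept + Xa %*% model@coefficients)
  names(pred) <- rownames(Xval)
  if (n_unmatched > 0)
    message(n_unmatched, " training feature(s) missing from the validation ",
            "matrix; imputed as 0")
  if (length(pred) < 3L || sd(pred) == 0 || sd(yval) == 0)
    return(list(accuracy = NA_real_, predictions = pred,
                n_unmatched = n_unmatched,
                reason = "zero variance in predictions (all-shrunk model)"))
  list(accuracy = cor(pred, yval), predictions = pred,
       n_unmatched = n_unmatched)
}

#' Null distribution of accuracy from random contig subsets
#'
#' Per replicate, draws `subsetSize` contigs uniformly without replacement
#' from the full (post-prevalence-filter) feature universe, refits the
#' L1-penalized model with the same penalty strategy, and records the
#' validation Pearson accuracy. The observed accuracy of the
#' metaGWAS-selected model is then placed on this distribution as a
#' percentile rank (which is invariant to any monotone transformation of
#' the null sample).
#'
#' @param Xtrain,y training abundance matrix and phenotype.
#' @param Xval,yval validation abundance matrix and phenotype.
#' @param subsetSize contigs per replicate (e.g. the number of contigs
#'   significant in the metaGWAS, mirroring a 422-for-FE / 619-for-DMI
#'   style design).
#' @param nReplicates number of random subsets (default 1000).
#' @param seed integer RNG seed (drives both the subset draws and the CV
#'   fold assignments, in replicate order).
#' @param lambdaStrategy,lambdaValue,folds penalty selection, as in
#'   [selectLambda()].
#' @param observed observed accuracy to rank (optional; may be set later).
#' @return a [NullDistribution-class].
#' @export
randomContigNull <- function(Xtrain, y, Xval, yval, subsetSize,
                             nReplicates = 1000L, seed = 1L,
                             lambdaStrategy = c("cv", "fixed"),
                             lambdaValue = NULL, folds = 5L,
                             observed = NA_real_) {
  lambdaStrategy <- match.arg(lambdaStrategy)
  Xtr <- .predictorMatrix(Xtrain)
  Xv <- .predictorMatrix(Xval)
  subsetSize <- as.integer(subsetSize)
  p <- ncol(Xtr)
  if (subsetSize > p)
    stop("subsetSize (", subsetSize, ") exceeds the feature universe (", p, ")")
  acc <- rep(NA_real_, nReplicates)
  set.seed(as.integer(seed))
  for (b in seq_len(nReplicates)) {
    idx <- sample.int(p, subsetSize)
    Xs <- Xtr[, idx, drop = FALSE]
    lam <- if (lambdaStrategy == "fixed")
      selectLambda(Xs, y, strategy = "fixed", lambda = lambdaValue)
    else selectLambda(Xs, y, strategy = "cv", folds = folds)
    model <- fitLasso(Xs, y, lambda = lam)
    acc[b] <- suppressMessages(predictValidation(model, Xv, yval)$accuracy)
  }
  new("NullDistribution", accuracies = acc, subsetSize = subsetSize,
      observed = observed, seed = as.integer(seed))
}

#' @rdname NullDistribution-class
#' @export
setMethod("replicateAccuracies", "NullDistribution", function(x) x@accuracies)

#' @rdname NullDistribution-class
#' @export
setMethod("observedAccuracy", "NullDistribution", function(x) x@observed)

#' @rdname NullDistribution-class
#' @export
setMethod("percentileRank", "NullDistribution", function(x) {
  if (is.na(x@observed)) return(NA_real_)
  acc <- x@accuracies[!is.na(x@accuracies)]
  100 * mean(acc <= x@observed)
})

setMethod("show", "NullDistribution", function(object) {
  acc <- object@accuracies[!is.na(object@accuracies)]
  ci <- quantile(acc, c(0.025, 0.975), names = FALSE)
  cat(sprintf("NullDistribution: %d replicates of %d random contigs\n",
              length(object@accuracies), object@subsetSize))
  cat(sprintf("  accuracy %.3f +/- %.3f, central 95%% interval [%.3f, %.3f]\n",
              mean(acc), sd(acc), ci[1], ci[2]))
  if (!is.na(object@observed))
    cat(sprintf("  observed accuracy %.3f at percentile %.1f\n",
                object@observed, percentileRank(object)))
})

#' Summary statistics of a null distribution
#'
#' @param x a [NullDistribution-class].
#' @return a list: `mean`, `sd`, `ci95` (2.5%/97.5% quantiles),
#'   `observed`, `percentile`.
#' @export
nullSummary <- function(x) {
  stopifnot(is(x, "NullDistribution"))
  acc <- x@accuracies[!is.na(x@accuracies)]
  list(mean = mean(acc), sd = sd(acc),
       ci95 = quantile(acc, c(0.025, 0.975), names = FALSE),
       observed = x@observed, percentile = percentileRank(x))
}

#' Serialize a LassoModel as TSV
#'
#' Writes a `feature_id` / `coefficient` table preceded by `#`-prefixed
#' header lines recording the intercept, penalty, training size and
#' standardization flag.
#'
#' @param model a [LassoModel-class].
#' @param path output path.
#' @export
writeLassoModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# intercept\t%.10g", model@intercept),
    sprintf("# lambda\t%.10g", model@lambda),
    sprintf("# n_train\t%d", model@nTrain),
    sprintf("# standardized\t%s", model@standardized),
    "feature_id\tcoefficient"), con)
  if (length(model@coefficients))
    writeLines(sprintf("%s\t%.10g", names(model@coefficients),
                       model@coefficients), con)
  invisible(path)
}

setMethod("show", "LassoModel", function(object) {
  cat(sprintf("LassoModel: %d/%d nonzero coefficients, lambda = %.4g, n = %d\n",
              length(object@coefficients), length(object@featureIds),
              object@lambda, object@nTrain))
})
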