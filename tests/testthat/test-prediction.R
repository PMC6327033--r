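softThreshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

test_that("a large enough penalty shrinks every coefficient to exactly zero", {
  set.seed(2)
  X <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- rnorm(30)
  lmax <- lambdaMax(X, y)
  m <- fitLasso(X, y, lmax * 1.0000001)
  expect_length(m@coefficients, 0)
  expect_equal(m@intercept, mean(y))
  # just below lambda_max something enters
  m2 <- fitLasso(X, y, lmax * 0.95)
  expect_gt(length(m2@coefficients), 0)
})

test_that("orthonormal designs reduce to soft-thresholding", {
  set.seed(8)
  Q <- qr.Q(qr(matrix(rnorm(20 * 5), 20, 5)))
  colnames(Q) <- paste0("f", 1:5)
  y <- rnorm(20)
  lam <- 0.012
  m <- fitLasso(Q, y, lam, standardize = FALSE, intercept = FALSE)
  beta <- setNames(numeric(5), colnames(Q))
  beta[names(m@coefficients)] <- m@coefficients
  oracle <- softThreshold(as.numeric(crossprod(Q, y)), 20 * lam)
  expect_equal(unname(beta), oracle, tolerance = 1e-8)
})

test_that("KKT conditions hold at convergence", {
  set.seed(3)
  n <- 40; p <- 25
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- X[, 1] * 1.5 - X[, 2] + rnorm(n, 0, 0.5)
  lam <- 0.08
  m <- fitLasso(X, y, lam)
  # reconstruct the standardized working problem
  Xc <- sweep(X, 2, m@center, "-")
  Xs <- sweep(Xc, 2, m@scale, "/")
  beta_std <- setNames(numeric(p), colnames(X))
  beta_std[names(m@coefficients)] <- m@coefficients * m@scale[names(m@coefficients)]
  r <- (y - mean(y)) - Xs %*% beta_std
  g <- abs(crossprod(Xs, r))
  active <- beta_std != 0
  expect_true(all(g[!active] <= n * lam + 1e-6))
  expect_true(all(abs(g[active] - n * lam) <= 1e-6))
})

test_that("objective matches a generic convex solver on duplicated columns", {
  set.seed(11)
  n <- 40
  X <- matrix(rnorm(n * 12), n, 12)
  X <- cbind(X, X[, 1:2])
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- X[, 1] * 2 - X[, 3] + rnorm(n, 0, 0.5)
  lam <- 0.05
  m <- fitLasso(X, y, lam, standardize = FALSE)
  g <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                      intercept = TRUE, thresh = 1e-14)
  obj <- function(b0, b) 0.5 * sum((y - b0 - X %*% b)^2) + n * lam * sum(abs(b))
  bfull <- setNames(numeric(ncol(X)), colnames(X))
  bfull[names(m@coefficients)] <- m@coefficients
  expect_equal(obj(m@intercept, bfull),
               obj(as.numeric(g$a0), as.numeric(g$beta)), tolerance = 1e-6)
})

test_that("invalid LASSO inputs are refused", {
  X <- matrix(rnorm(30), 10, 3)
  expect_error(fitLasso(X, rnorm(10), 0), "lambda")
  expect_error(fitLasso(X, rnorm(10), -1), "lambda")
  expect_error(fitLasso(X, c(rnorm(9), NA), 0.1), "finite")
  expect_error(fitLasso(X[1:2, ], rnorm(2), 0.1), "3")
})

test_that("cross-validated lambda tracks the signal-to-noise regime", {
  # pure noise: the chosen penalty stays near lambda_max
  near_max <- vapply(1:30, function(i) {
    set.seed(700 + i)
    X <- matrix(rnorm(30 * 40), 30, 40)
    y <- rnorm(30)
    lam <- selectLambda(X, y, "cv", folds = 5)
    lam >= 0.25 * lambdaMax(X, y)
  }, logical(1))
  expect_gte(mean(near_max), 0.9)

  # strong signal, low noise: the penalty drops well below lambda_max
  small <- vapply(1:30, function(i) {
    set.seed(800 + i)
    X <- matrix(rnorm(40 * 30), 40, 30)
    y <- X[, 1] * 2 + X[, 2] - X[, 3] + rnorm(40, 0, 0.1)
    lam <- selectLambda(X, y, "cv", folds = 5)
    lam < lambdaMax(X, y) / 10
  }, logical(1))
  expect_gte(mean(small), 0.9)

  expect_equal(selectLambda(NULL, NULL, "fixed", lambda = 0.37), 0.37)
  expect_error(selectLambda(matrix(rnorm(20), 4), rnorm(4), "cv",
                            folds = 10), "folds")
})

test_that("validation prediction matches the linear form and handles mapping", {
  set.seed(5)
  Xtr <- matrix(abs(rnorm(30 * 20, 10, 3)), 30, 20,
                dimnames = list(NULL, paste0("c", 1:20)))
  y <- Xtr[, 1] * 0.5 - Xtr[, 2] * 0.3 + rnorm(30, 0, 0.2)
  m <- fitLasso(Xtr, y, 0.05)
  # affine function of the linear predictor gives r = 1
  Xv <- matrix(abs(rnorm(15 * 20, 10, 3)), 15, 20,
               dimnames = list(paste0("v", 1:15), paste0("c", 1:20)))
  eta <- m@intercept + Xv[, names(m@coefficients), drop = FALSE] %*%
    m@coefficients
  res <- predictValidation(m, Xv, 3 + 2 * eta)
  expect_equal(res$accuracy, 1, tolerance = 1e-12)
  expect_equal(unname(res$predictions), unname(as.numeric(eta)))
  expect_equal(res$n_unmatched, 0)

  # missing validation features are zero-imputed and counted
  keep <- setdiff(colnames(Xv), names(m@coefficients)[1])
  expect_message(res2 <- predictValidation(m, Xv[, keep], rnorm(15)),
                 "missing")
  expect_equal(res2$n_unmatched, 1)

  # an all-shrunk model has no usable predictions
  m0 <- fitLasso(Xtr, y, lambdaMax(Xtr, y) * 1.01)
  res0 <- predictValidation(m0, Xv, rnorm(15))
  expect_true(is.na(res0$accuracy))
  expect_match(res0$reason, "variance")
})

test_that("the random-contig null replays an independently coded loop", {
  set.seed(6)
  p <- 50
  Xtr <- matrix(abs(rnorm(20 * p, 10, 3)), 20, p,
                dimnames = list(NULL, paste0("c", 1:p)))
  y <- Xtr[, 1] - Xtr[, 2] + rnorm(20, 0, 1)
  Xv <- matrix(abs(rnorm(12 * p, 10, 3)), 12, p,
               dimnames = list(NULL, paste0("c", 1:p)))
  yv <- rnorm(12)
  nd <- randomContigNull(Xtr, y, Xv, yv, subsetSize = 10L,
                         nReplicates = 20L, seed = 13L,
                         lambdaStrategy = "fixed", lambdaValue = 0.1)
  # oracle: same sampling order, fits through the public API
  set.seed(13L)
  oracle <- vapply(1:20, function(b) {
    idx <- sample.int(p, 10L)
    mod <- fitLasso(Xtr[, idx, drop = FALSE], y, 0.1)
    suppressMessages(predictValidation(mod, Xv, yv)$accuracy)
  }, numeric(1))
  expect_equal(replicateAccuracies(nd), oracle)
  expect_error(randomContigNull(Xtr, y, Xv, yv, subsetSize = p + 1L,
                                nReplicates = 2L, seed = 1L), "exceeds")
})

test_that("percentile rank is monotone-invariant and centered at the median", {
  acc <- seq(-0.5, 0.5, length.out = 101)
  nd <- new("NullDistribution", accuracies = acc, subsetSize = 10L,
            observed = stats::median(acc), seed = 1L)
  expect_equal(percentileRank(nd), 100 * mean(acc <= stats::median(acc)))
  expect_gt(percentileRank(nd), 49); expect_lt(percentileRank(nd), 52)
  # monotone transformation of the null sample leaves the rank unchanged
  tr <- function(x) tanh(2 * x)
  nd2 <- new("NullDistribution", accuracies = tr(acc), subsetSize = 10L,
             observed = tr(stats::median(acc)), seed = 1L)
  expect_equal(percentileRank(nd2), percentileRank(nd))
  s <- nullSummary(nd)
  expect_named(s, c("mean", "sd", "ci95", "observed", "percentile"))
})

test_that("model serialization round-trips through the TSV header", {
  set.seed(9)
  X <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- X[, 1] + rnorm(30, 0, 0.3)
  m <- fitLasso(X, y, 0.05)
  tf <- tempfile(fileext = ".tsv")
  writeLassoModel(m, tf)
  lines <- readLines(tf)
  expect_match(lines[1], "intercept")
  tab <- read.delim(tf, comment.char = "#")
  expect_setequal(tab$feature_id, names(m@coefficients))
  expect_equal(setNames(tab$coefficient, tab$feature_id)[names(m@coefficients)],
               m@coefficients, tolerance = 1e-9, ignore_attr = TRUE)
})
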