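# Naive O(n^3) average-linkage oracle on a precomputed distance matrix,
# agglomerating the closest pair (lowest index on ties) and averaging
# pairwise distances across cluster members.
naiveUpgma <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    idx <- which(active)
    for (i in idx) for (j in idx) if (i < j) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best - 1e-15) { best <- d; bi <- i; bj <- j }
    }
    heights[step] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    active[bj] <- FALSE
  }
  sort(heights)
}

test_that("duplicate animals merge first at height zero", {
  a <- twoBlobMatrix(seed = 3)
  av <- abundanceValues(a)
  av[, 2] <- av[, 1]  # exact duplicate pair
  m <- AbundanceMatrix(av, unit = "counts")
  d <- hcluster(m)
  expect_lt(d@hclust$height[1], 1e-12)
  first <- clusterEdges(d)$signature[1]
  expect_identical(first, paste(sort(colnames(av)[1:2]), collapse = "|"))
})

test_that("the top split of well-separated blobs recovers the blobs", {
  m <- twoBlobMatrix(nPerBlob = 2, seed = 11)
  d <- hcluster(m)
  cl <- stats::cutree(d@hclust, k = 2)
  expect_equal(length(unique(cl[1:2])), 1L)
  expect_equal(length(unique(cl[3:4])), 1L)
  expect_false(cl[1] == cl[3])
})

test_that("merge heights equal the naive average-linkage oracle", {
  set.seed(23)
  a <- matrix(rnorm(10 * 6, 20, 5), nrow = 10,
              dimnames = list(sprintf("f%d", 1:10), sprintf("cow%d", 1:6)))
  m <- AbundanceMatrix(abs(a), unit = "counts")
  d <- hcluster(m)
  D <- 1 - stats::cor(abundanceValues(m))
  expect_equal(sort(d@hclust$height), naiveUpgma(D), tolerance = 1e-10)
})

test_that("zero-variance animal profiles are refused by name", {
  a <- abundanceValues(twoBlobMatrix(seed = 2))
  a[, 3] <- 5
  expect_error(hcluster(AbundanceMatrix(a, unit = "counts")), "cow03")
})

test_that("scale-1 bootstrap probabilities replay an independent count oracle", {
  set.seed(61)
  a <- matrix(abs(rnorm(6 * 5, 10, 3)), nrow = 6,
              dimnames = list(sprintf("f%d", 1:6), sprintf("cow%d", 1:5)))
  m <- AbundanceMatrix(a, unit = "counts")
  scales <- c(1, 0.7)
  b <- 200L
  d <- multiscaleBootstrap(m, scales = scales, bPerScale = b, seed = 99L)

  # independent resample-and-count oracle with the same seed and the same
  # resampling order (scale-major, replicate-minor)
  leafsets <- function(hc) {
    n <- length(hc$labels)
    sets <- vector("list", n - 1L)
    for (i in seq_len(n - 1L)) {
      pick <- function(j) if (j < 0) hc$labels[-j] else sets[[j]]
      sets[[i]] <- sort(c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2])))
    }
    vapply(sets, paste, character(1), collapse = "|")
  }
  base_sig <- leafsets(stats::hclust(stats::as.dist(1 - stats::cor(a)),
                                     method = "average"))
  counts <- setNames(numeric(length(base_sig)), base_sig)
  set.seed(99L)
  for (s in scales) {
    m_r <- ceiling(s * nrow(a))
    for (i in seq_len(b)) {
      idx <- sample.int(nrow(a), m_r, replace = TRUE)
      cc <- suppressWarnings(stats::cor(a[idx, , drop = FALSE]))
      cc[is.na(cc)] <- 0
      hb <- stats::hclust(stats::as.dist(1 - cc), method = "average")
      if (s == 1) counts <- counts + (base_sig %in% leafsets(hb))
    }
  }
  ed <- clusterEdges(d)
  expect_equal(ed$bp1, unname(counts[ed$signature] / b), tolerance = 1e-12)
})

test_that("scale-1 BP is unchanged by the trailing scales (same seed)", {
  m <- twoBlobMatrix(nFeat = 12, nPerBlob = 3, noise = 2, seed = 5)
  d1 <- multiscaleBootstrap(m, scales = c(1, 0.8), bPerScale = 150L, seed = 4L)
  d2 <- multiscaleBootstrap(m, scales = c(1, 1.2, 0.6), bPerScale = 150L,
                            seed = 4L)
  expect_equal(clusterEdges(d1)$bp1, clusterEdges(d2)$bp1)
})

test_that("an always-recovered edge has BP 1 at all scales and AU 1", {
  a <- twoBlobMatrix(seed = 9)
  av <- abundanceValues(a)
  av[, 2] <- av[, 1]  # identical pair of animals on all features
  m <- AbundanceMatrix(av, unit = "counts")
  d <- multiscaleBootstrap(m, scales = c(0.6, 1, 1.4), bPerScale = 120L,
                           seed = 10L)
  ed <- clusterEdges(d)
  pair_sig <- paste(sort(colnames(av)[1:2]), collapse = "|")
  i <- which(ed$signature == pair_sig)
  expect_length(i, 1L)
  bp <- S4Vectors::metadata(ed)$bp_by_scale
  expect_true(all(bp[pair_sig, ] == 1))
  expect_equal(ed$au[i], 1)
  expect_equal(ed$bp1[i], 1)
  # the root edge contains all leaves in every replicate too
  root <- which.max(ed$n_leaves)
  expect_equal(ed$au[root], 1)
  # support values and dendrogram are reproducible from the seed
  d2 <- multiscaleBootstrap(m, scales = c(0.6, 1, 1.4), bPerScale = 120L,
                            seed = 10L)
  expect_identical(clusterEdges(d2)$au, ed$au)
  expect_identical(S4Vectors::metadata(clusterEdges(d2))$bp_by_scale, bp)
})

test_that("strong two-group structure earns high AU support on the top split", {
  m <- twoBlobMatrix(nFeat = 60, nPerBlob = 6, shift = 5, noise = 0.6,
                     seed = 13)
  d <- multiscaleBootstrap(m, bPerScale = 300L, seed = 21L)
  ed <- clusterEdges(d)
  blob1 <- paste(sort(sprintf("cow%02d", 1:6)), collapse = "|")
  blob2 <- paste(sort(sprintf("cow%02d", 7:12)), collapse = "|")
  expect_gte(ed$au[ed$signature == blob1], 0.95)
  expect_gte(ed$au[ed$signature == blob2], 0.95)
})

test_that("cluster accuracy counts the best label assignment", {
  m <- twoBlobMatrix(nPerBlob = 15, shift = 5, noise = 0.5, seed = 17)
  d <- hcluster(m)
  truth <- setNames(rep(c("HIGH", "LOW"), each = 15), sampleIds(m))
  expect_equal(clusterAccuracy(d, truth)@accuracy, 1.0)
  # one mislabeled animal of 30
  truth2 <- truth; truth2[1] <- "LOW"
  expect_equal(clusterAccuracy(d, truth2)@accuracy, 29 / 30)
  expect_error(clusterAccuracy(d, truth, k = 31), "exceeds")

  # random labels: mean accuracy matches the max-over-permutations
  # baseline computed by a Monte-Carlo counting oracle on the same cut
  cl <- stats::cutree(d@hclust, 2)
  set.seed(88)
  obs <- replicate(300, {
    clusterAccuracy(d, setNames(sample(truth), names(truth)))@accuracy
  })
  oracle <- replicate(1000, {
    lab <- sample(rep(c("HIGH", "LOW"), each = 15))
    tab <- table(cl, lab)
    max(sum(diag(tab)), sum(tab[1, 2], tab[2, 1])) / 30
  })
  expect_lt(abs(mean(obs) - mean(oracle)), 0.02)
})

test_that("PCA scores match an eigen-decomposition oracle up to sign", {
  set.seed(19)
  a <- matrix(abs(rnorm(3 * 4, 10, 2)), nrow = 3,
              dimnames = list(sprintf("f%d", 1:3), sprintf("cow%d", 1:4)))
  m <- AbundanceMatrix(a, unit = "counts")
  sc <- pcaScores(m)
  X <- scale(t(a), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(X))
  oracle <- X %*% ev$vectors[, 1:2]
  for (j in 1:2) {
    same <- isTRUE(all.equal(unname(sc[, j]), unname(oracle[, j]),
                             tolerance = 1e-8))
    flipped <- isTRUE(all.equal(unname(sc[, j]), -unname(oracle[, j]),
                                tolerance = 1e-8))
    expect_true(same || flipped)
  }
  expect_equal(unname(colMeans(sc)), c(0, 0), tolerance = 1e-10)

  m2 <- twoBlobMatrix(seed = 29)
  sc2 <- pcaScores(m2)
  expect_false(any(sign(sc2[1:5, 1]) == sign(sc2[6:10, 1])))
})

test_that("nested intake clustering recovers planted within-group structure", {
  set.seed(47)
  nFeat <- 40; n <- 24
  # outer FE signal on features 1-20, inner DMI signal on features 21-40;
  # per-feature effects vary in size and sign (a uniform offset would be
  # invisible to correlation distance)
  fe_class <- rep(c(1, 0), each = n / 2)
  dmi_class <- rep(rep(c(1, 0), each = n / 4), 2)
  base <- abs(rnorm(nFeat, 20, 2))
  fe_eff <- c(runif(20, 1.5, 2.5) * sample(c(-1, 1), 20, TRUE), rep(0, 20))
  dmi_eff <- c(rep(0, 20), runif(20, 1.5, 2.5) * sample(c(-1, 1), 20, TRUE))
  a <- vapply(seq_len(n), function(i) {
    pmax(base + fe_eff * fe_class[i] + dmi_eff * dmi_class[i] +
           rnorm(nFeat, 0, 1.2), 0)
  }, numeric(nFeat))
  dimnames(a) <- list(sprintf("f%02d", 1:nFeat), sprintf("cow%02d", 1:n))
  m <- AbundanceMatrix(a, unit = "counts")

  dmi <- 20 + 4 * dmi_class + rnorm(n, 0, 0.3)
  fe <- 1.1 + 0.4 * fe_class + rnorm(n, 0, 0.03)
  phen <- PhenotypeTable(data.frame(
    animal_id = colnames(a), milk_yield = fe * dmi, dmi = dmi,
    body_weight = 650, parity = "multiparous", population = "ref",
    fe = fe, group = ifelse(fe_class == 1, "HIGH", "LOW"),
    stringsAsFactors = FALSE))

  assoc_dmi <- metaGWAS(m, ifelse(dmi_class == 1, "HIGH", "LOW"))
  res <- nestedGroupClustering(m, phen, assoc_dmi, innerTrait = "dmi")
  expect_named(res, c("HIGH", "LOW"))
  expect_gte(res$HIGH$accuracy@accuracy, 0.9)
  expect_gte(res$LOW$accuracy@accuracy, 0.9)
  expect_true(all(grepl("^[HL]-[HL]dmi$", res$HIGH$labels)))

  # degenerate outer group is skipped with a warning
  phen_small <- PhenotypeTable(within(as.data.frame(phen),
                                      group[1:(n - 2)] <- "LOW"))
  expect_warning(nestedGroupClustering(m, phen_small, assoc_dmi),
                 "skipped")
})
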