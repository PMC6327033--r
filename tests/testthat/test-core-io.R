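test_that("cpmNormalize matches per-row arithmetic and preserves zeros", {
  m <- AbundanceMatrix(matrix(c(1, 3), nrow = 2,
                              dimnames = list(c("a", "b"), "s1")),
                       unit = "counts")
  expect_equal(as.numeric(abundanceValues(cpmNormalize(m))),
               c(250000, 750000))

  m2 <- AbundanceMatrix(matrix(c(5, 0, 5), nrow = 3), unit = "counts")
  expect_equal(as.numeric(abundanceValues(cpmNormalize(m2))),
               c(500000, 0, 500000))

  set.seed(3)
  a <- matrix(rpois(30 * 200, 25), nrow = 200)
  m3 <- cpmNormalize(AbundanceMatrix(a, unit = "counts"))
  # independent per-sample arithmetic
  expected <- vapply(seq_len(30), function(j) a[, j] / sum(a[, j]) * 1e6,
                     numeric(200))
  expect_equal(unname(abundanceValues(m3)), expected, tolerance = 1e-12)
  expect_true(all(abs(colSums(abundanceValues(m3)) - 1e6) <= 1))
  expect_identical(abundanceUnit(m3), "cpm")
})

test_that("cpmNormalize rejects empty libraries naming the sample", {
  a <- matrix(c(1, 2, 0, 0), nrow = 2,
              dimnames = list(c("a", "b"), c("good", "empty")))
  m <- AbundanceMatrix(a, unit = "counts")
  expect_error(cpmNormalize(m), "empty")
  expect_error(cpmNormalize(cpmNormalize(AbundanceMatrix(
    matrix(1:4, 2), unit = "counts"))), "counts")
})

test_that("prevalenceFilter keeps exactly the features at or above threshold", {
  set.seed(9)
  n <- 30
  a <- rbind(
    seven = c(rep(1, 7), rep(0, n - 7)),
    six = c(rep(1, 6), rep(0, n - 6)),
    allzero = rep(0, n),
    dense = rpois(n, 10) + 1
  )
  colnames(a) <- sprintf("s%02d", 1:n)
  m <- AbundanceMatrix(a, unit = "counts")
  f <- prevalenceFilter(m, 7L)
  expect_setequal(featureIds(f), c("seven", "dense"))
  expect_setequal(droppedFeatures(f), c("six", "allzero"))
  # column (feature) order preserved
  expect_identical(featureIds(f), c("seven", "dense"))
  expect_error(prevalenceFilter(m, n + 1L), "exceeds")
  # all-zero feature dropped at any threshold
  expect_false("allzero" %in% featureIds(prevalenceFilter(m, 1L)))
})

test_that("deriveFE is elementwise milk over intake", {
  p <- toyPhenotypes(30, seed = 1)
  fe <- deriveFE(p)$fe
  expect_equal(fe, p$milk_yield / p$dmi)
  one <- PhenotypeTable(data.frame(animal_id = "a", milk_yield = 30, dmi = 20,
                                   body_weight = 600, parity = "multiparous",
                                   population = "x"))
  expect_equal(deriveFE(one)$fe, 1.5)
  dry <- PhenotypeTable(data.frame(animal_id = "d", milk_yield = 0, dmi = 18,
                                   body_weight = 600, parity = "multiparous",
                                   population = "x"))
  expect_equal(deriveFE(dry)$fe, 0)
})

test_that("deriveRFI reproduces closed-form OLS residuals", {
  # single-predictor toy: dmi on milk. Normal equations by hand:
  # slope = cov/var = 2.5, intercept = mean(dmi) - 2.5 * mean(milk)
  p <- PhenotypeTable(data.frame(
    animal_id = c("a", "b", "c"), milk_yield = c(1, 2, 3), dmi = c(2, 4, 7),
    body_weight = 600, parity = "multiparous", population = "x"))
  r <- deriveRFI(p, predictors = "milk_yield")$rfi
  slope <- 2.5
  intercept <- mean(c(2, 4, 7)) - slope * 2
  expect_equal(r, c(2, 4, 7) - (intercept + slope * c(1, 2, 3)),
               tolerance = 1e-12)
  expect_lt(abs(sum(r)), 1e-9)

  # perfect linear dependence: all residuals zero
  p2 <- PhenotypeTable(data.frame(
    animal_id = letters[1:4], milk_yield = c(1, 2, 3, 4),
    dmi = 3 + 2 * c(1, 2, 3, 4), body_weight = 600,
    parity = "multiparous", population = "x"))
  expect_equal(deriveRFI(p2, predictors = "milk_yield")$rfi, rep(0, 4),
               tolerance = 1e-10)
})

test_that("RFI residuals are orthogonal to predictors and centered per population", {
  set.seed(21)
  p <- toyPhenotypes(40, seed = 5)
  df <- as.data.frame(p)
  df$population <- rep(c("A", "B"), each = 20)
  p <- PhenotypeTable(df)
  out <- deriveRFI(p)
  n <- nrow(out)
  for (pop in c("A", "B")) {
    i <- out$population == pop
    expect_lt(abs(mean(out$rfi[i])), 1e-9)
    expect_lt(abs(sum(out$rfi[i] * out$milk_yield[i])), 1e-6 * n)
    expect_lt(abs(sum(out$rfi[i] * out$body_weight[i]^0.75)), 1e-6 * n)
  }
  # collinear design errors, naming the predictors
  expect_error(deriveRFI(p, predictors = c("milk_yield", "milk_yield")),
               "milk_yield")
})

test_that("assignGroups labels extremes, is idempotent, warns on boundary ties", {
  p <- deriveFE(toyPhenotypes(30, seed = 2))
  # overwrite fe with 1..30 in scrambled order for determinism
  fe_vals <- sample(1:30)
  d2 <- as.data.frame(p); d2$fe <- fe_vals / 20; d2$milk_yield <- d2$fe * d2$dmi
  p <- PhenotypeTable(d2)

  g <- assignGroups(p, "fe", 15L)
  expect_identical(sort(unique(g$group)), c("HIGH", "LOW"))
  expect_identical(g$group[order(-g$fe)],
                   rep(c("HIGH", "LOW"), each = 15))
  # idempotent
  expect_identical(assignGroups(g, "fe", 15L)$group, g$group)
  # partial assignment leaves the middle unassigned
  g5 <- assignGroups(p, "fe", 5L)
  expect_equal(sum(g5$group == "unassigned"), 20)
  expect_error(assignGroups(p, "fe", 16L), "exceeds")

  # boundary tie
  d3 <- as.data.frame(p)[1:4, ]
  d3$fe <- c(2, 2, 1, 0.5); d3$milk_yield <- d3$fe * d3$dmi
  expect_warning(assignGroups(PhenotypeTable(d3), "fe", 1L), "tie")
})

test_that("abundance and phenotype files round-trip, salmon tables assemble", {
  m <- toyCounts()
  tf <- tempfile(fileext = ".tsv")
  writeAbundanceTable(m, tf)
  m2 <- readAbundanceTable(tf, unit = "counts")
  expect_equal(abundanceValues(m2), abundanceValues(m))

  p <- toyPhenotypes()
  cf <- tempfile(fileext = ".csv")
  writePhenotypeTable(p, cf)
  p2 <- readPhenotypeTable(cf)
  expect_equal(p2$milk_yield, p$milk_yield)
  expect_identical(p2$animal_id, p$animal_id)

  # per-sample quantification tables -> counts matrix (union of features)
  q1 <- tempfile(fileext = ".sf"); q2 <- tempfile(fileext = ".sf")
  writeLines(c("Name\tLength\tEffectiveLength\tTPM\tNumReads",
               "cA\t500\t450\t10\t100", "cB\t300\t250\t5\t50"), q1)
  writeLines(c("Name\tLength\tEffectiveLength\tTPM\tNumReads",
               "cA\t500\t450\t20\t200", "cC\t800\t750\t1\t10"), q2)
  mq <- readSalmonQuants(c(q1, q2), sampleIds = c("s1", "s2"))
  expect_identical(abundanceUnit(mq), "counts")
  expect_equal(abundanceValues(mq)["cB", ], c(s1 = 50, s2 = 0))
  expect_equal(abundanceValues(mq)["cA", ], c(s1 = 100, s2 = 200))
})

test_that("the pipeline applies the documented order: filter counts, then CPM", {
  # the two orders differ whenever a dropped feature carries counts, so
  # equality with filter-then-normalize pins the documented order
  sim <- simulateCohorts(smallSimConfig(31L, nContigs = 200L))
  res <- suppressWarnings(
    runPipeline(PipelineConfig(rngSeed = 31L), data = sim, runNull = FALSE))
  manual <- cpmNormalize(prevalenceFilter(sim$ref$abundance, 7L))
  ig <- selectTopPercentile(infoGainTable(manual, res$phenotypes), 95)
  expect_identical(res$infogain$feature_id, ig$feature_id)
  expect_equal(res$infogain$ig_bits, ig$ig_bits)
})

test_that("AbundanceMatrix validity enforces units and uniqueness", {
  expect_error(AbundanceMatrix(matrix(-1, 1, 1), unit = "counts"),
               "non-negative")
  expect_error(AbundanceMatrix(matrix(1:4, 2, 2,
                                      dimnames = list(c("a", "a"), NULL)),
                               unit = "counts"), "unique")
  # cpm label requires per-sample closure to 1e6
  expect_error(AbundanceMatrix(matrix(c(1, 2), 2, 1), unit = "cpm"), "1e6|sum")
  ok <- AbundanceMatrix(matrix(c(4e5, 6e5), 2, 1), unit = "cpm")
  expect_s4_class(ok, "AbundanceMatrix")
})
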