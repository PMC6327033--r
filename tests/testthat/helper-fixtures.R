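# Shared fixtures, built in code.

# Small deterministic count matrix (features x samples).
toyCounts <- function(nFeat = 8, nSamp = 6, seed = 42) {
  set.seed(seed)
  a <- matrix(rpois(nFeat * nSamp, lambda = 40), nrow = nFeat,
              dimnames = list(sprintf("c%02d", seq_len(nFeat)),
                              sprintf("cow%02d", seq_len(nSamp))))
  AbundanceMatrix(a, unit = "counts")
}

toyPhenotypes <- function(n = 6, seed = 42) {
  set.seed(seed)
  PhenotypeTable(data.frame(
    animal_id = sprintf("cow%02d", seq_len(n)),
    milk_yield = round(runif(n, 20, 40), 1),
    dmi = round(runif(n, 15, 25), 1),
    fat_pct = round(rnorm(n, 3.8, 0.2), 2),
    protein_pct = round(rnorm(n, 3.3, 0.2), 2),
    body_weight = round(rnorm(n, 650, 30)),
    parity = rep(c("primiparous", "multiparous"), length.out = n),
    population = "herd1",
    stringsAsFactors = FALSE
  ))
}

# A two-blob matrix where the first half of the animals share one profile
# and the second half another, plus noise; strong clustering signal.
twoBlobMatrix <- function(nFeat = 40, nPerBlob = 5, shift = 6, noise = 0.3,
                          seed = 7) {
  set.seed(seed)
  base <- rnorm(nFeat, 10, 1)
  eff <- c(rep(shift, nFeat / 2), rep(0, nFeat / 2))
  n <- 2 * nPerBlob
  a <- vapply(seq_len(n), function(i) {
    base + (if (i <= nPerBlob) eff else -eff) + rnorm(nFeat, 0, noise)
  }, numeric(nFeat))
  a <- pmax(a, 0)
  dimnames(a) <- list(sprintf("f%02d", seq_len(nFeat)),
                      sprintf("cow%02d", seq_len(n)))
  AbundanceMatrix(a, unit = "counts")
}

# Fast small simulation for property tests.
smallSimConfig <- function(seed, nContigs = 300L, nInformative = 20L,
                           effectSize = 1.5, ...) {
  SimulationConfig(nContigs = nContigs, nInformative = nInformative,
                   effectSize = effectSize,
                   librarySizeRange = c(2e4, 5e4), rngSeed = seed, ...)
}

latentClass <- function(sim, cohort = "ref") {
  S4Vectors::metadata(sim$truth)[[paste0(cohort, "_class")]]
}
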