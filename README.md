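# rumenMGWAS

Metagenome-wide association and cross-population prediction of feed
efficiency from rumen contig abundances.

## What this is for

Feed efficiency (FE = milk yield / dry matter intake, kg/kg) is one of
the most economically and environmentally important traits in dairy
cattle, and one of the hardest to record: individual intake measurement
needs specialized equipment few farms have. The rumen microbiome
digests the feed, and its composition tracks how efficiently a cow
converts feed into milk — which makes a metagenome sample a candidate
*proxy phenotype* for FE and intake.

`rumenMGWAS` is an R package for quantitative geneticists and microbiome
researchers who want to run that analysis chain on sample-by-contig
abundance matrices (e.g. assembled-contig quantifications of rumen
shotgun libraries):

- **CPM normalization** and **prevalence filtering** of raw count
  matrices (`cpmNormalize()`, `prevalenceFilter()`), plus readers for
  TSV matrices and SALMON-style per-sample quantification tables;
- **phenotype derivation**: FE, residual feed intake (RFI = observed −
  expected DMI from a within-population regression on milk yield and
  metabolic body weight), and HIGH/LOW extreme-group assignment;
- **information-gain pre-selection**: per contig, the Gaussian-entropy
  reduction in bits
  `IG = log2(sd_pooled · sqrt(2πγ)) − Σ_s (N_s/N) log2(sd_s · sqrt(2πγ))`
  with maximum-likelihood SDs (the constant γ cancels; IG ≥ 0), keeping
  the top 5%;
- **metaGWAS**: per-contig logistic regression of the HIGH/LOW group on
  CPM with Wald tests at α = 0.05, with complete and quasi-separation
  flagged rather than silently mis-tested;
- **cluster support**: UPGMA over animals on correlation distance with
  multiscale-bootstrap BP and approximately unbiased (AU) p-values
  (probit extrapolation `Φ⁻¹(1−BP_r) ≈ v√r + c/√r`, `AU = 1−Φ(v−c)`),
  two-group classification accuracy, nested intake-within-efficiency
  clustering, and PCA scores;
- **cross-population prediction**: an L1-penalized linear model
  `min ½‖y − y₀ − Xβ‖² + nλ‖β‖₁` (compiled coordinate descent,
  cross-validated λ) trained on a reference herd and evaluated by
  Pearson accuracy in an independent herd, ranked against a
  **random-contig null distribution**;
- a **synthetic cohort generator** (`simulateCohorts()`) that emulates
  the two-herd study design with planted, partially shared
  contig–phenotype signal, so the whole pipeline is testable without
  sequence data.

## Worked example

```r
library(rumenMGWAS)

res <- runPipeline(PipelineConfig(rngSeed = 7L, nNullReplicates = 200L))

show(res$manifest)
#> RunManifest
#>   funnel: n_features=2000 -> after_prevalence=1999 -> after_infogain=100 -> significant=59
#>   seeds: simulate=160162, groups=264891, bootstrap=369620, lambda=474349, null=579078

res$clusterAccuracy@accuracy
#> [1] 0.8
res$validation$accuracy
#> [1] 0.5346669

show(res$null)
#> NullDistribution: 200 replicates of 59 random contigs
#>   accuracy 0.101 +/- 0.219, central 95% interval [-0.286, 0.494]
#>   observed accuracy 0.535 at percentile 98.6
```

Reading the output: of 2,000 simulated contigs, 1,999 survive the
7-of-30 prevalence filter, the top 100 (5%) pass the information-gain
screen, and 59 are significantly associated with the FE group at
α = 0.05. Clustering the reference animals on those 59 contigs
classifies them into the (noisily assigned) HIGH/LOW FE groups with
accuracy 0.80. The L1-penalized model trained on them predicts FE in the
independent 31-cow validation herd with Pearson accuracy 0.53, while 200
random 59-contig subsets average 0.10 — random metagenome content
carries *some* information about efficiency, but the selected contigs
sit at the 98.6th percentile of that null.

Each stage is also available as a standalone function (`metaGWAS()`,
`multiscaleBootstrap()`, `fitLasso()`, `randomContigNull()`, …) and the
bootstrap dendrogram can be serialized to Newick with AU/BP annotations
(`writeDendrogram()`). A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

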