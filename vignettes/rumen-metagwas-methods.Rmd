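---
title: "Classifying and predicting feed efficiency from rumen metagenome abundances: models and methods"
author: "rumenMGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and predicting feed efficiency from rumen metagenome abundances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis this package implements

Dairy cows that convert feed into milk efficiently host measurably
different rumen microbial communities than inefficient ones. Because
recording individual dry matter intake (DMI) is expensive, the rumen
metagenome is attractive as a *proxy phenotype*: if contig abundances
track feed efficiency (FE = milk yield / DMI, kg/kg), a metagenome sample
could stand in for weeks of intake recording.

`rumenMGWAS` implements the full analysis chain for this idea on
sample-by-contig abundance matrices:

1. **Normalization and filtering** (`cpmNormalize()`, `prevalenceFilter()`):
   raw mapped-read counts per contig are scaled to counts per million
   (CPM) within each sample; contigs observed in too few animals are
   removed *before* normalization (quantify, filter, then CPM — the
   totals of the retained contigs define the library).
2. **Phenotype derivation** (`deriveFE()`, `deriveRFI()`,
   `assignGroups()`): FE as the milk/intake ratio; residual feed intake
   (RFI) as the residual of a within-population ordinary least-squares
   regression of DMI on milk yield and metabolic body weight
   (`body_weight^0.75`); HIGH/LOW groups as the top and bottom
   `nPerTail` animals on the chosen trait.
3. **Information-gain pre-selection** (`infoGainTable()`,
   `selectTopPercentile()`): an agnostic entropy-reduction screen
   (below) keeps the top 5% of contigs.
4. **metaGWAS** (`metaGWAS()`): a per-contig logistic regression of group
   (HIGH = 1) on the contig's CPM, Wald-tested at α = 0.05.
5. **Cluster support** (`hcluster()`, `multiscaleBootstrap()`,
   `clusterAccuracy()`, `nestedGroupClustering()`, `pcaScores()`):
   UPGMA over animals on correlation distance, with multiscale-bootstrap
   BP/AU support per cluster and two-group classification accuracy.
6. **Cross-population prediction** (`fitLasso()`, `selectLambda()`,
   `predictValidation()`, `randomContigNull()`): an L1-penalized linear
   model trained on the reference herd predicts phenotypes of a distinct
   validation herd; its Pearson accuracy is ranked against a
   random-contig-subset null distribution.

`runPipeline()` orchestrates all stages from one configuration with a
single root seed and returns a manifest recording the feature funnel and
the per-stage derived seeds.

# The information-gain screen

For a contig with CPM values split by the binary phenotype, entropy is
modeled on a Gaussian scale in bits:

$$H(\sigma) = \log_2\!\left(\sigma\sqrt{2\pi\gamma}\right),$$

and the information gain is the pooled-versus-within entropy difference

$$IG = H(\sigma_{pooled}) - \frac{N_H\,H(\sigma_H) + N_L\,H(\sigma_L)}{N_H + N_L}.$$

Three numerical choices matter here.

* **The constant γ cancels.** Whether γ is read as the Euler–Mascheroni
  constant (0.5772…) or as Euler's number $e$ (as in the Gaussian
  differential entropy $\tfrac12\log 2\pi e\sigma^2$), the
  $\log_2\sqrt{2\pi\gamma}$ term appears with weight one in both parts
  of the difference and cancels exactly. The package defaults to the
  Euler–Mascheroni constant and exposes it only so the invariance can be
  tested; IG values are identical to machine precision under either
  reading.
* **Maximum-likelihood SDs.** All SDs divide by $N$, not $N-1$. With ML
  estimates the pooled variance equals the weighted within-group
  variance plus the between-group variance, and the weighted AM–GM
  inequality then guarantees $IG \ge 0$ — the "entropy reduction"
  interpretation holds on every input. With sample SDs small groups
  could produce spuriously negative gains.
* **Degenerate contigs are kept, not dropped.** A contig constant within
  one group separates the groups perfectly: it gets $IG = +\infty$ and
  ranks first. A contig constant overall carries no information:
  $IG = 0$. Both are flagged in the `degenerate` column.

Selection keeps the top `ceiling((100 - percentile) * n / 100)` ranked
contigs. The subtraction is done in that order because
`1 - 95/100` is not representable in binary floating point and a
one-ulp excess would inflate the ceiling (5% of 100 contigs must be 5,
not 6). For 175,969 contigs at the 95th percentile this convention
yields 8,799 — the only convention consistent with that printed pair.
Ranks use `ties.method = "first"` (stable input order) so they are a
permutation of `1..n`; a gain tie straddling the selection boundary is
resolved by that order with a warning.

# Per-contig logistic association

Each pre-selected contig is tested with
`glm(group ~ cpm, family = binomial)`, HIGH coded 1, and the Wald z test
on the slope. Choices and caveats:

* **Predictor scale.** The CPM enter untransformed (z-standardized by
  default purely for numerical stability; the Wald statistic is
  invariant to affine rescaling and the standardization flag is recorded
  in the result). No log or rank transform is applied by default — the
  abundance itself is the modeled covariate.
* **Multiplicity.** The default significance rule is raw α = 0.05 per
  contig, which is statistically liberal across thousands of tests;
  `p_adjust = "BH"` switches the `significant` flag to
  Benjamini–Hochberg-adjusted p-values for users who want control of the
  false discovery rate.
* **Separation.** A contig whose group ranges do not overlap has a
  divergent maximum-likelihood slope (complete separation); a contig
  that drives fitted probabilities to 0/1 (glm's diagnostic) has a Wald
  SE that diverges faster than the estimate, so the test silently
  *loses* power exactly where the signal is strongest (the Hauck–Donner
  effect). Both cases are flagged `separation = TRUE` with the p-value
  reported missing-with-reason, and such contigs are excluded from the
  clustering input — the pathology stays visible instead of being
  absorbed by a penalized fit. glm runs with `epsilon = 1e-12` so that
  reported standard errors are evaluated at the converged estimate.
* **Taxa.** `taxaAssociation()` models a taxon's *relative abundance* as
  the response of a quasi-binomial logit regression on group + parity
  (appropriate for proportions in [0,1]) and reports the group-effect
  p-value; `direction = "group"` flips response and covariate for users
  who prefer the group-as-outcome reading. A fully parity-confounded
  design triggers a rank-deficiency warning.

# Multiscale bootstrap cluster support

Animals are clustered by average linkage (UPGMA) on correlation distance
$1 - r_{Pearson}$ between their contig-CPM profiles — the conventional
defaults of multiscale bootstrap clustering tools. *Features* (contigs)
are resampled; *animals* are clustered.

For each scale $r \in \{0.5, 0.6, \ldots, 1.4\}$, $\lceil r\,p\rceil$
contigs are drawn with replacement $B$ times (default 1,000) and the
animals re-clustered; an edge's bootstrap probability $BP_r$ is the
fraction of replicate trees containing its exact leaf set. The
approximately unbiased p-value extrapolates across scales on the probit
scale: $\psi(r) = \Phi^{-1}(1 - BP_r)$ is fitted as
$v\sqrt{r} + c/\sqrt{r}$ by weighted least squares with binomial weights
$B\,\phi(\psi_r)^2 / (BP_r(1 - BP_r))$, and $AU = 1 - \Phi(v - c)$.
Geometrically, $v$ estimates the (signed) distance of the data from the
boundary of the region in which the observed cluster forms and $c$ its
curvature; AU corrects BP's well-known bias toward conservatism for
large clusters.

Numerical choices:

* Boundary proportions are moved off 0/1 by $(count + 0.5)/(B + 1)$
  before the probit transform (reported BP values stay raw).
* An edge recovered in *every* replicate at *every* scale has $AU = 1$
  by definition, and one never recovered has $AU = 0$ with a diagnostic
  flag; the probit fit is skipped in both cases (it is undefined on a
  constant boundary-corrected curve).
* The RNG is consumed scale-major, replicate-minor, so a run whose
  `scales` vector shares a prefix with another run at the same seed
  reproduces those scales' resamples exactly; everything is
  bit-reproducible from `(input, seed, scales, bPerScale)`.
* A bootstrap subsample can leave an animal with a constant profile;
  its undefined correlations are treated as 0 (distance 1) within the
  resampling loop only. On the observed data a constant profile is an
  error naming the animal.

Classification accuracy cuts the tree into $k$ groups (`cutree`) and
reports the best concordant fraction over cluster-to-label assignments.
An interpretation note: "cluster support below the conventional 0.05
level" corresponds to $1 - AU < 0.05$, i.e. $AU \ge 0.95$.

# L1-penalized cross-population prediction

The reference herd's selected contigs train
$$\hat\beta = \arg\min_\beta\; \tfrac12\lVert y - y_0 - X\beta\rVert^2
  + n\lambda\lVert\beta\rVert_1,$$
solved by cyclic coordinate descent (compiled; soft-threshold updates,
unpenalized intercept via centering, features z-standardized with
coefficients mapped back to the CPM scale). Convergence is declared when
no coefficient moves more than `1e-8` in a sweep; at
$\lambda \ge \lambda_{max} = \max_j |x_j^\top(y - \bar y)|/n$ the exact
solution is the all-zero model. Karush–Kuhn–Tucker conditions at the
solution are property-tested, and on duplicated-column designs the
objective value (not the non-unique coefficient split) is checked
against an independent solver.

Because no penalty value is prescribed by the analysis this package
reproduces, λ is chosen by 5-fold cross-validation on a 50-point
log-spaced grid from $\lambda_{max}$ downward — four decades when
$n > p$, stopping at $\lambda_{max}/100$ when $p \ge n$ (the near-zero
end of the path is an ill-posed interpolating fit there).

Validation animals are predicted as $\hat y^* = y_0 + x^*\hat\beta$ with
features matched by contig id; contigs absent from the validation
quantification are imputed as 0 CPM with a logged count (cross-population
mapping is rarely complete), and validation CPM are standardized with the
*training* statistics, the standard choice when the validation cohort
must not influence the model. Accuracy is the Pearson correlation between
predicted and observed phenotypes.

The **random-contig null** repeats the whole fit on subsets of contigs
drawn uniformly without replacement from the full post-prevalence-filter
universe — deliberately *not* from the information-gain pool, so the
selected contigs are contrasted against generic metagenome content,
which itself carries diffuse information about intake and efficiency.
The observed accuracy is reported as a percentile of the null sample,
a rank that is invariant to monotone transformation of the null.

# The synthetic cohort generator

`simulateCohorts()` makes the pipeline testable without external
sequence data. It emulates a two-herd design: a reference herd of 30
cows with two latent efficiency classes of 15, and a validation herd of
31 cows under a different diet/environment.

Generative model, per cohort:

* Per-contig baseline log-abundances are drawn once,
  $\log\mu_j \sim N(0, 1.5)$ (natural log), giving the heavy-tailed
  abundance spectrum typical of shotgun contig quantifications.
  Validation baselines are the reference baselines plus $N(0, 0.3)$
  noise — community composition shifts with environment while the
  abundance spectrum is preserved.
* 50 of 2,000 contigs are informative: their log-mean shifts between
  latent classes by `effectSize` (default 1.5) within-class SDs of the
  log-intensity noise, half the shift on each side, sign random per
  contig. In the validation cohort only `sharedFraction` (default 0.6)
  of these effects persist; the rest revert to baseline.
* Counts are compositional: per animal, gamma intensities with shape
  $1/\phi$ (dispersion φ default 0.5, i.e. count variance
  $\mu + \phi\mu^2$) are drawn around the class-specific means, then a
  multinomial distributes an integer library size (uniform on
  100,000–300,000) across contigs. Sample sums equal library sizes
  exactly while per-contig counts stay negative-binomial-like.
* Only 85% of reference contigs appear in the validation matrix,
  exercising the id-matching and zero-imputation path.
* FE phenotypes are drawn at class means 1.5 vs 1.1 kg/kg with
  within-class SD 0.156, so that extreme-group assignment on observed FE
  agrees with the latent class for roughly 90% of animals — group labels
  carry realistic phenotype noise rather than leaking the truth; DMI is
  drawn independently at 22 ± 2 kg/d and milk yield is FE × DMI.

What the generator does **not** emulate: read-level error, sequence
content, taxonomic correlation structure among contigs (each contig is
conditionally independent given its class), herd structure, or
lactation-stage trends. Passing recovery tests therefore show that the
statistics behave as designed under a clean compositional signal model —
not that real rumen data will reach the same accuracies.

Two practical consequences of this design are worth knowing. First, the
~90% label-noise choice caps the achievable FE-group classification
accuracy near 0.9 even when the latent classes are recovered perfectly.
Second, with heavy-tailed baselines a handful of high-abundance contigs
dominate raw-CPM Pearson correlations, and average linkage then
occasionally cuts a two-cluster tree into one outlier animal versus the
rest; this is a faithful property of the published procedure (raw-CPM
correlation distance, UPGMA), not of the support computation.

# Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `minPrevalence` | 7 | samples | observed-in-7-of-30 rule; the equivalent 25%-of-animals rule is `ceiling(0.25 * n)` |
| `igPercentile` | 95 | percent | keep the top 5% by information gain |
| `alpha` | 0.05 | — | per-contig significance; BH adjustment optional |
| `bootScales` | 0.5–1.4 × 0.1 | ratio of p | multiscale grid bracketing scale 1 |
| `nBootReplicates` | 1000 | replicates/scale | AU probit fit stability |
| `lambdaStrategy` | `"cv"` | cv / fixed | no penalty value is prescribed; CV is the principled default |
| `nNullReplicates` | 1000 | replicates | null density resolution |
| `effectSize` | 1.5 | within-class SDs | planted log-abundance shift |
| `sharedFraction` | 0.6 | fraction | effects persisting across populations |
| `dispersion` | 0.5 | φ in var = μ+φμ² | overdispersed shotgun-like counts |

# Problem sizes used by the test suite and acceptance script

The shipped tests simulate 200–2,000 contigs and 20–30 animals per
cohort, run the multiscale bootstrap at up to 400 features × 30 animals ×
10 scales × 1,000 replicates, and evaluate the random-contig null with
200 replicates; calibration and power properties use 20–200 replicate
simulations. These sizes were chosen as the smallest at which the
statistical properties under test (calibration, monotonicity, recovery)
are stable, and `scripts/acceptance.R` uses the full default study design
(2,000 contigs, 30 + 31 cows) with the 200-replicate null.

# Known limitations

* Raw α = 0.05 over thousands of contigs is liberal by construction;
  the BH option exists but is off to match the reproduced procedure.
* Wald tests at n = 30 are approximate, and quasi-separated contigs
  yield no p-value at all (flagged); a likelihood-ratio alternative
  would retain power there but is not the reproduced procedure.
* The LASSO's coefficient split across strongly correlated contigs is
  non-unique; only predictions and the objective are stable, and no
  biological meaning should be read into which of two collinear contigs
  carries the weight.
* Separated (perfectly classifying) contigs are excluded from the
  clustering input by design, so with very strong planted effects the
  clustering can paradoxically see only the weaker half of the signal.
* No mixed models, no covariates in the contig metaGWAS, no elastic
  net or stability selection: the scope is the published chain.
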