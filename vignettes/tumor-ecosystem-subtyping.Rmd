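---
title: "Tumor ecosystem subtyping from network-propagated mutations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor ecosystem subtyping from network-propagated mutations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tesnet)
```

## The problem

A tumor's somatic mutation profile is, per patient, a sparse binary vector:
a few dozen mutated genes out of hundreds sequenced, with little overlap
between patients even within one disease. Clustering such vectors directly
is hopeless — two patients hitting different members of the same pathway
look maximally dissimilar. tesnet implements a subtyping strategy that
resolves this in three moves: smooth each patient's mutation vector over a
protein-interaction network, summarize the smoothed profile at the level of
tumor-ecosystem gene sets, and only then cluster. The resulting clusters are
called tumor ecosystem subtypes (TES); by convention TES 1 is the
better-prognosis cluster.

## Network propagation

Let $W$ be the column-stochastic transition matrix of the interaction
network (adjacency columns divided by their sums) and $p_0$ the restart
distribution of a sample: uniform mass $1/m$ over the sample's $m$ mutated
genes that are present in the network. The random walk with restart iterates

$$p_{t+1} = (1 - r)\,W p_t + r\,p_0,$$

with restart probability $r = 0.75$, stopping when
$\lVert p_{t+1} - p_t \rVert_1 < 10^{-6}$. The steady state
$p_\infty = r\,(I - (1-r)W)^{-1} p_0$ is a probability distribution over all
network genes that concentrates near the mutated genes but leaks mass to
their network neighborhood, which is exactly the smoothing we need. Because
$(1-r)W$ has spectral radius at most $1-r = 0.25$, the iteration contracts
geometrically; at the default tolerance it converges in around ten steps,
and the iteration cap of 10,000 exists only to catch a mis-built $W$.

Numerical choices made here, where the update rule itself leaves room:

* **Residual norm.** The stopping rule uses the L1 norm, which measures
  probability mass moved per step and is the common convention for
  random-walk iterations.
* **Seed normalization.** Uniform over in-network mutated genes; it is the
  parameter-free choice, and mutation counts are deliberately not used as
  weights (a mutated gene either seeds the walk or it does not).
* **Edge weights.** Interaction confidence scores are thresholded
  (strictly greater than 700 on the 0–1000 scale) and the surviving
  adjacency is unweighted by default; `weighted = TRUE` divides columns by
  their weighted sums instead. Unweighted is the default because
  thresholding already enforces high confidence and makes results
  insensitive to the score calibration of a particular network release.
* **Samples with empty seeds** (no mutated gene in the network) are
  excluded from propagation and reported, never silently dropped.
* Batched (matrix) and per-sample iteration give the same trajectory; the
  tests pin the two against each other and against the direct linear solve.

## Gene-set scoring

Each propagated profile is scored against a collection of tumor-ecosystem
gene sets by single-sample GSEA. Genes are ranked by propagated value in
decreasing order and assigned the rank-from-bottom statistic (the top gene
gets rank $N$); a running sum steps up by $\mathrm{rank}^{\alpha} / \sum_{
\text{in set}} \mathrm{rank}^{\alpha}$ at in-set genes and down by
$1/(N - |S|)$ otherwise, and the enrichment score is the *integrated* running
difference (its sum over all $N$ positions), not the maximal deviation. The
exponent is $\alpha = 0.25$, the established single-sample GSEA default.
Raw scores are normalized to NES by dividing by the range
$\max(ES) - \min(ES)$ taken over the whole cohort matrix: global-range
normalization keeps NES comparable across samples, which the clustering
step requires.

Ties in propagated values (common at exactly zero for genes unreachable
from any seed) are broken by gene-name lexicographic order so that scores
are deterministic. Genes in a set but absent from the profile are ignored,
with a per-set coverage attribute; a set with no overlap at all scores `NA`
with a warning rather than failing the run.

## Survival filtering and clustering

Every gene set's NES column is tested for association with overall survival
by a univariate Cox proportional-hazards model (Breslow tie handling, Wald
p-values — the defaults of the survival package, which backs this layer);
sets with $p < 0.05$ are kept, and each is annotated as risk
($\beta > 0$) or protective. The filter is computed on the training
partition and frozen for any test data. Dimensionality reduction by
prognostic filtering is a pragmatic choice: it removes gene sets that carry
no survival-relevant signal before the distance-based clustering sees them.

Patients are then clustered by K-means (Euclidean) on the kept NES columns
for each $k \in \{2, \dots, 10\}$, and the $k$ with the largest mean
silhouette width is selected. Further choices:

* **Column standardization.** NES columns are z-scored before K-means
  (exposed as `standardize`); without it, sets with larger NES ranges
  dominate the Euclidean metric.
* **Initialization.** `stats::kmeans` with 25 random restarts per $k$ and a
  per-$k$ seed stream. Multi-start random initialization gives the
  stability that matters here — the selected $k$ and labels are
  reproducible under the recorded seed, and the restarts make the
  silhouette argmax insensitive to any single bad start.
* **Label orientation.** K-means numbering is arbitrary, so labels are
  canonicalized: clusters are ordered by Kaplan-Meier restricted-mean
  survival (restricted at the largest observed time), largest first, so
  TES 1 is always the better-prognosis cluster. Ties are broken by cluster
  size, then original label index.

Subtypes are characterized by a log-rank test between TES survival curves,
two-sided Wilcoxon rank-sum comparisons of every gene set's NES between the
two TESs (exact enumeration when both groups have at most ten samples,
normal approximation with tie correction otherwise; significance stars at
0.05/0.01/0.001), and a differential analysis of the propagated gene values
at $|\log_2 FC| > 1$ and $p < 0.05$. Propagated values live on a
probability scale that can contain exact zeros, so the fold change is
regularized as $\log_2\!\big((\bar{x}_1 + \varepsilon)/(\bar{x}_2 +
\varepsilon)\big)$ with $\varepsilon$ equal to $10^{-3}$ times the smallest
positive value in the profile; a gene with both group means zero reports a
fold change of 0 and a flag. Raw p-values are reported throughout
(Benjamini-Hochberg is available via `stats::p.adjust` on the returned
tables but is not applied by default).

## The classifier

A gradient-boosted tree classifier (xgboost) assigns TES labels to new
samples from NES features alone. The defaults are the grid-search winners
for this task: learning rate 0.1, 100 trees, depth 3, column subsampling
0.8, binary logistic objective, seed 123. Evaluation is stratified 10-fold
cross-validation — stratified because small synthetic cohorts otherwise
risk empty-class folds — and both the mean of per-fold accuracies and the
pooled held-out accuracy are reported, along with a pooled confusion matrix
and ROC AUC. Feature attribution uses the tree-SHAP decomposition built
into xgboost, ranked by mean absolute value; a feature that is constant
across samples attributes exactly zero. Prediction aligns features by name,
so column order never matters and mismatched feature sets fail loudly.

## The synthetic cohort generator

The generator produces data with the statistical structure the pipeline
assumes, so every stage is testable end to end:

* **Network**: preferential attachment from a complete seed clique on
  $m + 1$ nodes, each new node attaching to $m$ distinct existing nodes
  with probability proportional to degree. This yields a connected graph
  with a heavy-tailed degree distribution — the property of real
  interaction networks that most affects random-walk behavior, since hubs
  soak up propagated mass. Edge count is deterministic:
  $\binom{m+1}{2} + m\,(n - m - 1)$. Edge weights are uniform on
  $[700, 1000]$, i.e. already high-confidence.
* **Mutations**: every gene mutates with a background probability of 0.02
  per sample; the driver genes of the sample's subtype mutate with
  probability 0.8. Samples drawing zero mutations are resampled (up to 100
  retries) so the cohort size stays exact.
* **Gene sets**: each subtype's 10-gene driver module is planted inside a
  distinct block of gene sets padded with random genes; the remaining sets
  are random draws of size 10–25. This makes both the prognostic filter
  and the clustering signal controllable.
* **Survival**: exponential with baseline hazard 0.02 per month and a
  multiplicative hazard ratio of 3 for subtype 2, independently censored
  at rate 0.01. The exponential/proportional-hazards form matches the Cox
  filter's assumption and has closed-form oracles (the per-group hazard
  MLE is events over time at risk), which the tests exploit.

Defaults — 300 samples, 300 genes, 2 subtypes, the rates above — are the
strong-planted-signal study conditions used by the test suite and the
acceptance script. Mutation sparsity is not hard-coded anywhere: the rates
are configuration, because real cohort sparsity varies by panel and tumor
type.

What the generator does **not** emulate: mutational signatures and
trinucleotide context, copy-number and structural variation, clinical
covariates beyond survival, the gene-panel censoring of real targeted
sequencing, and inter-gene mutation-rate covariation. Passing the planted
recovery tests therefore shows the pipeline is correct and sensitive under
its own model assumptions — not that real cohorts contain two clean
subtypes.

## Problem sizes and determinism

The test suite runs the full pipeline at 300 samples by 300 genes with 20
gene sets (a deliberate desk-scale choice; a real cohort with a
16,000-gene network is the same code path with a larger dense matrix), and
the statistics calibration checks use 500 null replicates. Every stochastic
component takes an explicit seed, and every stage is bit-reproducible under
it; run manifests record the seed and parameter set. The workflow is
exposed as package functions plus the numbered drivers under `analysis/`
rather than a shell wrapper — the drivers are the command-line surface.

## Known limitations

* The silhouette criterion cannot select $k = 1$; a cohort with no real
  structure will still be split, which is why the log-rank test between the
  resulting TESs should always be consulted.
* The Cox filter inherits the proportional-hazards assumption; strongly
  non-proportional prognostic sets can be filtered out.
* With $k > 2$ the two-group Wilcoxon characterization and the binary
  classifier are skipped; the clustering and log-rank stages still run.
* Gene identifiers are matched verbatim (case-sensitive, no alias
  resolution); any protein-to-gene mapping must happen upstream.
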