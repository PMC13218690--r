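# tesnet — tumor ecosystem subtyping from network-propagated somatic mutations

Somatic mutation calls are the cheapest and most widely available genomic
readout of a tumor, but per patient they form a sparse binary vector that
resists direct clustering. **tesnet** stratifies cancer cohorts into
**tumor ecosystem subtypes (TES)** from mutation data alone, for
computational oncologists who have panel sequencing and survival follow-up
but no expression profiling:

1. **Propagate.** Each patient's binary mutation vector seeds a random walk
   with restart over a high-confidence protein-interaction network,
   \(p_{t+1} = (1-r)\,W p_t + r\,p_0\) with restart probability
   \(r = 0.75\), column-stochastic transition matrix \(W\), and L1 stopping
   rule \(\lVert p_{t+1}-p_t\rVert_1 < 10^{-6}\). The steady state
   \(p_\infty\) is a continuous profile over all network genes.
2. **Score.** Propagated profiles are scored against tumor-ecosystem gene
   sets by single-sample GSEA (rank weight \(\alpha = 0.25\), integrated
   running-sum statistic) and normalized to NES by the global score range.
3. **Subtype.** Gene sets prognostic for overall survival (univariate Cox,
   Wald \(p < 0.05\)) are kept; patients are clustered by K-means with
   \(k \in 2..10\) selected by mean silhouette width; labels are oriented
   so TES 1 is the better-prognosis cluster; subtypes are contrasted by
   log-rank, per-set Wilcoxon rank-sum tests, and differential propagated
   genes (\(|\log_2 FC| > 1\), \(p < 0.05\)).
4. **Predict.** A gradient-boosted classifier (learning rate 0.1, 100
   trees, depth 3, column subsampling 0.8, stratified 10-fold CV) assigns
   TES labels to new samples from NES features, with mean-|SHAP| feature
   ranking.

A synthetic-cohort generator (scale-free network, planted driver modules,
exponential survival with a subtype hazard ratio) makes the whole pipeline
testable without restricted clinical data.

## Worked example

The numbered drivers under `analysis/` run the whole study on a synthetic
cohort (300 patients x 300 genes, two planted subtypes, hazard ratio 3):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_propagate.R
Rscript analysis/03_score.R
Rscript analysis/04_subtype.R
Rscript analysis/05_characterize.R
Rscript analysis/06_classify.R
```

`04_subtype.R` prints:

```
Prognostic filter kept 15 of 20 gene sets ( 8 risk / 7 protective )
Selected k = 2 by mean silhouette:
     2      3      4      5      6      7      8      9     10
0.5951 0.3728 0.1735 0.1635 0.1405 0.1341 0.1247 0.1260 0.1317
TES
  1   2
146 154
Log-rank between TESs: chi-square = 75.15 , p = 4.37e-18
Adjusted Rand index vs planted subtypes: 1
```

Read: of the 20 ecosystem gene sets, 15 carry survival signal and pass the
Cox filter; silhouette peaks at k = 2, recovering the two planted subtypes
exactly (ARI 1); the subtypes' survival curves separate decisively. The
classifier step then reports

```
10-fold CV accuracy: mean 0.9952, pooled 0.9952; AUC 1.0000
Held-out accuracy vs training-derived labels: 0.9889
```

i.e. once subtypes exist, NES features predict them almost perfectly, and
the SHAP ranking puts the driver-module gene sets on top.

The same stages are available as one call for in-memory or file inputs
(MAF-like TSV or count matrix, STRING-style links file, GMT, survival TSV):

```r
library(tesnet)
co  <- generate_cohort(synthetic_config(seed = 1))
res <- run_tes_pipeline(co$mutations, co$network, co$genesets, co$survival,
                        train_fraction = 0.7, seed = 1)
res$subtypes          # selected k, labels, silhouette trace
res$logrank           # survival separation between TESs
res$test_predictions  # classifier labels for the held-out partition
```

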