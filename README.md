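# sexbiasdev

Consensus detection, onset classification, and comparative analysis of
**sex-biased gene expression across organ development**.

Most studies of sexually dimorphic expression compare adult males and
females at a single time point.  In a developmental time series the
interesting questions are different: *when* does a sex difference first
appear relative to sexual maturity, is it organ-specific, is it
conserved across species, which cell types carry it, and which
transcription factors or chromatin regions sit upstream of it?
`sexbiasdev` implements a complete pipeline for these questions on
two-sex bulk RNA-seq time series (genes × samples counts with stage,
sex and replicate metadata), together with single-cell matrices,
ortholog maps and regulatory region sets — and a simulation layer that
generates every one of those inputs with known ground truth, so the
whole pipeline is validated against itself.

## The statistical core

* **Four time-series callers**, each testing the gene-wise null of no
  sex effect anywhere along development in the negative-binomial model
  `Y ~ NB(mu, alpha)`, `Var = mu + alpha*mu^2`:
  1. spline likelihood-ratio test
     (`~ sex + ns(stage, df) + sex:ns(stage, df)` vs `~ ns(stage, df)`),
  2. factor likelihood-ratio test
     (`~ sex + stage + sex:stage` vs `~ stage`), with Cox–Reid profile
     dispersions shrunk to a mean–dispersion trend and a
     moderated-denominator F reference,
  3. two-step polynomial regression on `log2(normalized + 0.5)`
     (sex-block F-test, backward elimination, `R^2 >= 0.6`),
  4. a stage-window permutation test,
     `T = max_w |mean_w d(t)| * sqrt(|w|)`, sex labels permuted within
     stage — built for effects confined to part of the series.
* **Consensus rule**: a gene is sex-biased when **at least two callers**
  are BH-significant at 0.05 *and* agree in direction.
* **Onset classes**: per-gene male-minus-female trajectories are
  peak-standardized, soft-clustered (fuzzy c-means, K by the
  fuzzy-partition-coefficient elbow), and each cluster's active window
  assigns *always sex-biased*, *pre-* or *post-sexual-maturity*.
* **Comparative layer**: organ-specificity index
  `tau = sum(1 - x_i/x_max)/(N-1)`, sex-chromosome chi-square
  enrichment, 1:1-ortholog overlap with a size-preserving permutation
  test, Wilcoxon effect-size comparisons, hypergeometric functional
  enrichment.
* **Cellular and regulatory layer**: expression-matched control-bin
  module scores per cell with per-cell-type male-vs-female Wilcoxon
  tests, and TSS-window (±3 kb) assignment of region sets to target
  genes with 2×2 enrichment tests.

## Worked example

```r
library(sexbiasdev)

# a two-sex series: 8 stages, 2 replicates/sex/stage, maturity at stage 6,
# 50 genes spiked with log2 fold changes 1-3 and mixed onset classes
design <- timeseries_design(n_genes = 500, n_stages = 8, maturity_stage = 6,
                            reps_per_sex_stage = 2, seed = 7)
spikes <- random_spikes(design, n_spiked = 50, lfc_values = c(1, 2, 3), seed = 8)
sim    <- simulate_timeseries(design, spikes)
ts     <- normalize_counts(sim$ts)
ts
#> ExpressionTimeSeries: 500 genes x 32 samples (8 stages, normalized)

results <- list(caller_spline_lrt(ts), caller_factor_lrt(ts),
                caller_poly2step(ts), caller_window_perm(ts, n_perm = 1000, seed = 9))
calls <- consensus(results, alpha = 0.05)
calls
#> SexBiasCallSet: 500 genes, 27 male-biased, 16 female-biased

evaluate_calls(calls, sim$truth)
#> EvaluationReport: TP=41 FP=2 TN=448 FN=9 | sens=0.820 spec=0.996 FDP=0.047
#> per-lfc sensitivity: lfc 1: 0.588, lfc 2: 0.882, lfc 3: 1.000

head(subset(calls$table, status != "unbiased"), 4)
#>      gene        status n_supporting                   callers        lfc  provenance
#> 13 g00013   male-biased            4 spline,factor,poly,window  2.0279710 time_series
#> 38 g00038 female-biased            4 spline,factor,poly,window -2.9783802 time_series
#> 49 g00049   male-biased            3        spline,factor,poly  0.9818417 time_series
#> 50 g00050 female-biased            4 spline,factor,poly,window -1.0181073 time_series
```

Of the 50 spiked genes, 41 are recovered with the correct direction;
the two false positives put the observed false-discovery proportion at
0.047, in line with the BH level of the consensus.  Sensitivity rises
from 0.59 at a log2 fold change of 1 to 1.00 at 3.  The consensus `lfc`
column is the median estimate across the supporting callers — compare
`g00013` (spiked at 2) and `g00038` (spiked at 3).

Onset classification of the called genes:

```r
biased <- subset(calls$table, status != "unbiased")$gene
tr <- difference_trajectories(ts, biased)
K  <- choose_k(tr$z, seed = 10)               # signed shapes: 2 per class
cl <- soft_cluster(tr$z, K, seed = 10)
onset <- classify_onset(cl, tr$stages, maturity_stage = 6)
table(onset$class)
#>  always_SB    post_SM     pre_SM unassigned
#>         15         16         10          2
```

The single call `run_all(pipeline_config(seed = 1), "out/")` reproduces
the full synthetic study — both organs, all callers, onset,
specificity, conservation, cells and regulation — and writes every
table plus a byte-stable `summary.json` keyed to the configuration
hash.

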