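---
title: "Detecting sex-biased expression across organ development: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-biased expression across organ development: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Genes whose expression differs between males and females ("sex-biased"
genes) underlie sexually dimorphic traits, yet single-snapshot
differential expression misses the developmental dimension: when a sex
difference first appears, whether it is transient, and whether it is
confined to particular cell types.  `sexbiasdev` implements a complete
analysis pipeline for two-sex developmental RNA-seq time series —
consensus calling over four complementary algorithms, onset
classification, organ specificity, cross-species conservation, cell-type
attribution, and regulatory-target enrichment — together with a
simulation layer that generates every input with known ground truth, so
each step can be validated end to end.

# The count model and the simulation layer

Bulk counts are modelled as negative binomial (NB): a gene $g$ in sample
$j$ has $Y_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g)$ with
$\mathrm{Var}(Y) = \mu + \alpha\mu^2$.  The simulator draws each gene's
log-mean stage trajectory from a cubic B-spline of the stage ordinal
(three interior knots, zero-mean Gaussian coefficients, default sd 0.35
on the natural-log scale), shared between the sexes; smooth,
organ-like dynamics arise without committing to a parametric shape.
Gene dispersions follow the familiar bulk trend
$\alpha(\mu) = a_0/\mu + a_1$ (defaults $a_0 = 3$, $a_1 = 0.05$) with
log-normal gene-level noise (sdlog 0.3).  Sequencing depth varies per
sample by a log-uniform factor in $[0.7, 1.3]$ around the library-size
target, which forces the normalization step to matter.

Sex effects are injected by **binomial thinning**: for a gene spiked
male-biased with log2 fold change $L$, every count of the female samples
inside the effect window is replaced by a $\mathrm{Binomial}(y, 2^{-L})$
draw.  Thinning preserves the NB family, scales the mean by exactly
$2^{-L}$ (so the realized expected fold change is exactly $2^L$), and
never invents reads; only the lower sex is ever touched.  The default
design — 8 stages from organogenesis to adulthood, 2 replicates per sex
per stage, sexual maturity declared at stage 6 — matches a well-powered
organ series of the kind the method targets (real series span 7–16
stages with 1–3 replicates per sex per stage).

What the simulation does *not* emulate: batch effects, outlier samples,
ambient RNA or doublets in the cell matrices, read-level error, and
species-specific assembly gaps (e.g. missing Y-linked genes).  Passing
tests therefore demonstrate correctness of the statistical machinery
under a clean generative model, not robustness to every artefact of
real data.

# The four callers

All callers share a normalization step (median-of-ratios size factors
against a geometric-mean pseudo-reference; upper-quartile fallback when
no gene is positive in all samples) and an expression filter: a gene is
tested only if its mean normalized count reaches 5 in at least one sex —
NB fits are unstable below that.

1. **Spline LRT** (`caller_spline_lrt`): NB GLM with
   $\log \mu = \log sf + \beta_0 + \beta_s\,\mathrm{sex} +
   f(\mathrm{stage}) + \mathrm{sex}{:}f(\mathrm{stage})$, $f$ a natural
   cubic spline with `df = 3`; the reduced model drops sex and the
   interaction ($df + 1$ numerator degrees of freedom).
2. **Factor LRT** (`caller_factor_lrt`): the same contrast with stage as
   a categorical factor (`~ sex + stage + sex:stage` vs `~ stage`,
   $S$ numerator df), the classical time-series LRT layout.
3. **Two-step polynomial** (`caller_poly2step`): least squares on
   $\log_2(\text{normalized count} + 0.5)$ with a centred stage
   polynomial; step 1 is an F-test of the sex block, step 2 backward
   elimination of sex terms at 0.05 plus an $R^2 \ge 0.6$ goodness
   filter.  The default degree is 3: organ trajectories are
   spline-shaped, and a quadratic leaves systematic lack-of-fit in the
   residual variance that makes the sex F-test conservative (null
   rejection ~0.024 instead of ~0.035 at $\alpha = 0.05$).  The 0.5
   pseudocount is the standard variance-stabilising choice on the log
   scale.
4. **Stage-window permutation** (`caller_window_perm`): the statistic is
   $\max_w |\bar d_w| \sqrt{|w|}$ over all contiguous stage windows
   $w$ of length $\ge 2$, where $d(t)$ is the stage-wise
   male-minus-female mean log2 difference; the null permutes sex labels
   within each stage; empirical p-values use add-one smoothing.  The
   window form targets effects confined to part of the series, such as
   post-maturity onsets.  A granularity limitation is worth knowing:
   the within-stage permutation group is finite, so a window of $L$
   stages at 2 replicates per sex has a p-value floor of about
   $2/\binom{4}{2}^L$ — effects confined to only two stages cannot
   reach $p < 0.05$ at that replication level.

## Dispersion estimation and small-sample calibration

Gene-wise dispersions are estimated by Cox–Reid-adjusted profile maximum
likelihood — the GLM coefficients are refitted at every candidate
$\alpha$, since profiling against fixed fitted means biases $\alpha$
low — and then shrunk on the log scale toward a robust trend
$\hat a_0/\mu + \hat a_1$ with weight $d/(d + d_0)$, where $d$ is the
residual df and $d_0 = 10$ a fixed prior weight; 1–3 replicates per
stage demand pooling.

Two further choices keep the tests honest at these sample sizes, both
adopted after measuring null calibration (the standing requirement for
every caller is that raw p-values are uniform-or-conservative under the
null):

* The LRT statistic over its df is referred to an
  $F(\mathrm{df},\, d + d_0)$ distribution rather than $\chi^2$.  The
  chi-square reference rejects ~0.10 at nominal 0.05 for the factor
  contrast (16 coefficients on 32 samples); the moderated-denominator F
  is the quasi-likelihood convention.
* A median-based scale factor (genomic-control style) divides the
  statistics: $\lambda = \max\!\big(1,\ \mathrm{median}(T)/
  (\mathrm{df}\cdot F^{-1}_{0.5})\big)$.  The clamp at 1 means it can
  only ever make the test more conservative, and the median is robust
  as long as most genes are not sex-biased — true in every organ the
  method is meant for.  The same clamped scaling (with a moderated-df t
  reference) applies to the stage-wise Wald test, which is otherwise
  substantially liberal on a 4-sample adult subset.

## Consensus, stage-wise calls, and the extended set

A gene is sex-biased when **at least two callers** are BH-significant at
$\alpha = 0.05$ *and* agree in direction; discordant significant pairs
do not count.  The consensus log2 fold change is the median of the
supporting callers' estimates (robust to one caller's outlier fit).  BH
adjustment is applied within each caller across the tested genes of one
organ-and-species run, mirroring the per-organ analysis structure.
Stage-wise (classical, single-snapshot) calls on the adult or prenatal
subset complement the time-series calls: the **extended set** is their
union, with provenance recorded per gene and direction conflicts
resolved in favour of the time-series call.  Adult-only calls typically
carry smaller effect sizes, which is exactly why the union recovers
them.

# Onset classification

For each sex-biased gene the difference trajectory
$d(t) = \overline{\log_2(\mathrm{nc}+0.5)}_{M}(t) -
\overline{\log_2(\mathrm{nc}+0.5)}_{F}(t)$ is standardized by its own
peak ($\max |d| = 1$), preserving sign.  Standardized trajectories are
soft-clustered by fuzzy c-means (fuzzifier $m = 2$, Euclidean distance,
20 seeded restarts; optimization by `e1071::cmeans`, with memberships
recomputed analytically from the final centers so zero-distance limits
are exact).  The number of clusters is chosen by scanning $K = 2..8$
and taking the elbow of the fuzzy partition coefficient — important in
practice because $C$ onset classes occur in both directions, giving up
to $2C$ distinct signed shapes.

Each cluster center, rescaled to its own peak, defines an *active
window*: stages where the scaled absolute effect reaches
`effect_threshold = 0.5` ("active" means at least half the gene's own
peak effect).  Active at every stage ⇒ **always sex-biased**; first
active stage at or after maturity minus one stage ⇒ **post sexual
maturity** (the one-stage tolerance captures onsets "around" maturity);
an earlier first active stage ⇒ **pre sexual maturity**.  The pre class
is onset-based deliberately: genes that start differing before maturity
and continue into adulthood belong with the early-onset class, so a
window straddling maturity is classified by where it starts.  Genes
inherit their maximum-membership cluster's class when that membership
reaches 0.5, otherwise they are unassigned; clusters with an empty
active window leave their genes unassigned.  The maturity stage is
supplied externally per species and organ — it is an annotation, not
something inferred from expression.

# Specificity and chromosome enrichment

The organ-specificity index is
$\tau = \sum_i (1 - x_i/x_{\max})/(N-1)$ over $N$ organs; 0 means
uniform expression, 1 single-organ.  By default $\tau$ is computed on
$\log_2(x+1)$-transformed per-organ means to damp dynamic-range
dominance (a `transform = "none"` flag gives the raw-scale index, on
which $\tau$ is exactly scale-invariant).  Genes with $\tau > 0.8$ are
flagged organ-specific.  Sex-chromosome enrichment of a call set uses a
2×2 Pearson chi-square without continuity correction when all expected
counts reach 5, Fisher's exact test otherwise; the universe is the set
of genes passing the expression filter, matching "genes tested".

# Conservation across species

Call sets are compared through 1:1 ortholog maps; genes biased in one
species are stratified into those with and without a 1:1 ortholog
(duplication or loss).  Overlap significance uses a permutation test:
null draws are random subsets of the 1:1 universe preserving both set
sizes, with add-one-smoothed empirical p-values
(`n_perm = 9999` by default, so p is never zero) and BH adjustment
across the family of comparisons run together.  The size-preserving
exchangeable null is the simplest defensible choice; a
sex-chromosome-stratified null would be a natural extension since
sex-linked genes dominate conserved calls, and the permutation machinery
accepts any universe the caller passes, so stratification can be
imposed by restricting the universe.  Effect-size comparisons between
call strata use the two-sided Wilcoxon rank-sum test (exact for groups
of ≤ 25 without ties); functional enrichment uses the upper-tail
hypergeometric with BH across categories, skipping categories with
fewer than 3 set members.

# Cell-type attribution

Single-cell matrices are normalized as
$\log(1 + 10^4\, c_{gj}/\mathrm{lib}_j)$, the common single-cell
convention.  A gene set's **module score** per cell is the mean
normalized expression over the set minus the mean over
expression-matched controls: genes are ranked into 24 equal-size bins by
average normalized expression, and each set gene contributes 100 control
genes sampled from its bin (never from the set itself, so adding a
constant to the set shifts scores by exactly that constant; bins smaller
than the control count are sampled with replacement, logged).
Summation residuals below $10^{-12}$ are reported as exact zeros.
Within each cell type with at least 20 cells of each sex, male and
female scores are compared by a two-sided Wilcoxon rank-sum test, BH
across types.  Cells are the test units, accepting pseudoreplication as
the cell-level captions of typical single-cell analyses do; differences
in cell-type *proportions* between sexes are deliberately not tested.
`setwise_specificity` ranks types by mean score and flags the top type
when its mean is positive and at least twice the runner-up — the
operational line between "expressed specifically in one type" (the
male-biased kidney pattern, proximal tubule) and "broadly expressed"
(the female-biased pattern).

# Regulatory targets

A region set (TF peaks, DNase-hypersensitive sites, chromatin marks) is
resolved to target genes through a symmetric half-open TSS window
$[\mathrm{tss} - w, \mathrm{tss} + w)$, default $w = 3$ kb — the common
promoter-annotation convention; strand is used only to locate the TSS.
Overlap is computed with interval trees (`GenomicRanges`) and verified
in tests against a brute-force all-pairs oracle, including boundaries
at exactly $w$.  Enrichment of a bias set among targets uses the same
2×2 chi-square/Fisher machinery as above, plus a coverage summary
(fraction of bias genes targeted by ≥ 1 set vs the expressed universe).
`directional_enrichment` crosses male/female bias sets with
sex-stratified region sets so concordant wiring — each sex's genes
enriched for its own stratum's targets — can be read off the grid
diagonal.

# Reproducibility and scale

Every stochastic stage derives its own stream from a single
configuration seed; `run_all()` writes all tables, the truth JSON, the
serialized configuration and its MD5 hash, and a `summary.json` that is
byte-identical across reruns with the same seed.  The default demo
study uses 800 genes × 8 stages × 2 replicates per sex per stage for
the bulk series, 1 200 genes × 1 200 cells for the cell matrix, 4 000
ortholog families, and 2 000 overlap permutations — sizes chosen so the
whole study, run twice for the determinism check, completes in a few
minutes on one CPU while leaving every statistical property measurable.
The validation suite uses 2 000-gene series with 200 spiked genes
(log2 fold changes 1–3 in equal parts, mixed onset classes), three
seeds for null calibration, five for onset recovery, and twenty for the
cell-type attribution runs.

# Known limitations

* The fourth caller is a window-permutation test designed for the same
  role as the original study's in-house algorithm (partial-window sex
  effects); it matches that role, not its unpublished letter, and has
  the p-value floor described above.
* Calibration was tuned for 2–3 replicates per sex per stage.
  Single-replicate (human-style) designs run but are low-powered; the
  callers emit no special handling for them.
* The onset classifier assumes the difference trajectories of one
  cluster share a class; heavily mixed clusters dilute into
  `unassigned` rather than mis-assign, which is the intended failure
  mode.
* Wrong-direction calls are counted as false positives by
  `evaluate_calls`, a stricter convention than set-overlap accuracy.
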