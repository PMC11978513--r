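---
title: "Benchmarking single-cell reference integration and query mapping"
author: "scMapBench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking single-cell reference integration and query mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scMapBench)
```

# The problem

Building a single-cell reference atlas involves integrating count matrices
from several batches (donors, technologies, sites) into one embedding, then
mapping held-out *query* batches into that space, transferring labels to the
query cells, and flagging query populations that the reference has never
seen. Choices made upstream — most prominently which features are kept —
change the quality of every one of those steps. scMapBench provides the
evaluation side of that problem: a data model for reference/query splits
with designated unseen populations, selected metrics covering five aspects
of quality, baseline-anchored scaling that makes metric scores comparable,
and a synthetic benchmark generator so the whole pipeline can be exercised
and tested without external data.

The package deliberately does *not* ship integration models. Real embeddings
(from conditional autoencoders, iterative clustering correctors, or anything
else) are consumed through the `JointEmbedding` container; a transparent
fixture integrator with a tunable residual batch effect stands in for them
so that metric behaviour can be validated against known ground truth.

# Data model and preprocessing

`CellMatrix` holds a cells x features count matrix with per-cell batch and
label factors; cells are rows everywhere, and every per-cell vector is
row-aligned, which removes a whole class of silent transposition bugs.
`SplitDataset` holds the reference and query halves with identical feature
order, the set of unseen labels, and a provenance log. I/O uses the AnnData
H5AD layout (dense or compressed-sparse `X`, `obs` annotations, `obsm`
embeddings) via a thin rhdf5 layer, plus TSV score tables.

`prepareSplit()` applies the preprocessing procedure in a fixed order:

1. cell quality control — cells with fewer than 100 total counts or fewer
   than 100 expressed features are removed;
2. reference/query split by batch;
3. labels with fewer than 20 cells are removed, applied to each half
   independently (an unseen label exists only in the query, so a per-half
   rule is the only consistent reading);
4. unseen labels are removed from the reference only;
5. features not expressed in any reference cell are dropped from both
   halves.

Each step logs its removal counts, the input/output totals balance exactly,
and the procedure is idempotent on its own output (both properties are
tested). The order matters — the label-size filter sees post-QC counts, and
the feature filter sees the unseen-free reference — so it is fixed rather
than configurable.

# The synthetic benchmark generator

`simulateCounts()` is a Poisson-gamma (negative binomial) count simulator in
the splat tradition: gamma base means per gene, per-label log-normal
differential expression factors applied with probability `de_prob`,
log-normal multiplicative batch effects, log-normal library sizes scaled by
a per-batch depth factor, and a biological coefficient of variation applied
through the gamma mixing step. Two features distinguish it from a vanilla
splat-style model. First, *label-specific extra noise*: a per-cell,
per-gene log-normal factor (unit mean, sd `noise_sd` per label) multiplied
into the expected expression before counts are drawn, so some populations
are intrinsically noisier than others. The distributional form of this
noise is this package's choice — multiplicative log-normal — selected for
being unit-mean and scale-free. Second, a two-branch trajectory: branch
cells get means interpolated between the progenitor profile and the branch
terminus, carry their interpolation step as metadata, and are labelled by
their branch segment, so a partially differentiated "Intermediate" state
can be designated unseen.

The default scenario mirrors a three-technology design: two batches of
medium depth and medium size, two small deep batches, and two large shallow
batches that form the query; ten labels including a progenitor with two
branches; and `Rare`, `Perturbed` and `Intermediate` present only in the
query. Cell numbers (tens of cells per label per batch, around 2,000 cells
and 1,000 features in total) are desk-scale by design: large enough for
every metric to be defined and stable, small enough that the full benchmark
runs in minutes on a laptop. The ground truth (differential expression
flags and factors, base means, library sizes, trajectory steps) is stored
in the provenance so selectors and metrics can be validated against it.

What the generator does *not* emulate: ambient RNA, doublets, cell-cycle
structure, zero inflation beyond the negative binomial, or realistic
gene-gene correlation. Passing tests on this generator therefore shows that
the metrics and selectors behave correctly where the truth is known — not
that any particular method will win on real tissue atlases.

`simulateEmbedding()` skips counts entirely and draws Gaussian label
clusters with batch offsets in latent space; unseen labels are placed
either at least six cluster standard deviations away from every center
("far") or on top of an existing center ("merged"). It exists purely to
give metrics oriented good/bad instances cheaply.

`fixtureIntegrate()` is the toy integrator: counts-per-10k, log1p, PCA
fitted on the reference with the query projected in, then each cell shifted
by `-removal * (batch mean - global mean)` in PC space. `removal = 0`
returns the uncorrected PCA (kept as the pre-integration embedding),
`removal = 1` centers batch means exactly, and intermediate values leave a
controlled residual batch effect — which is what makes monotonicity tests
of the batch metrics possible.

# Feature selectors

The bundled selectors are the simple strategies needed to drive the
pipeline: all features, seeded random sets, highest raw mean, highest raw
variance, a binned-dispersion highly-variable-gene ranking (counts-per-10k,
log1p, dispersion = variance/mean, z-scored within 20 equal-width mean
bins), and a variance-stabilising-transform style ranking (a degree-2
polynomial trend of log10 variance on log10 mean of raw counts, then the
variance of standardised values clipped at sqrt(n cells)). Every fixed-size
selector defaults to 2,000 features, the operating point recommended for
routine use. Random selection is always evaluated as five seeded sets whose
metric scores are averaged downstream.

`selectBatchAware()` runs a selector per batch and combines sets by the
number of batches choosing each feature, breaking ties by median
within-batch rank — the "selected by most batches" convention.

`wilcoxonMarkers()` is the supervised selector: per label, a Wilcoxon
rank-sum test of each feature (label vs rest) on log1p counts-per-10k,
removal of features expressed in under 10% of the label's cells or over
80% of cells outside it or with p above 0.1, ranking by estimated log2 fold
change, and the top 200 features per label. The per-label sets are combined
by union by default. An intersection rule is also implemented, but the
intersection of per-label marker lists is generically empty (a good marker
for one label is rarely a good marker for another), so union is the default
and the intersection path warns when it returns nothing. "Expressed" means
count > 0; the fold change uses expm1 of mean log-normalised values with a
1e-9 pseudocount — both conventions are stated here because they are
otherwise easy to leave implicit. P-values are used raw (no multiplicity
correction) since the cascade is a ranking filter, not an inference
procedure; the rank-sum test itself is a vectorised normal approximation
with tie and continuity correction that replicates `wilcox.test()` and is
unit-tested against it.

# Label transfer

`transferLabels()` fits an L2-regularised multinomial logistic regression
on the reference coordinates and labels (decay equivalent to inverse
regularisation strength C = 1, solver iterations capped at 1,000, relative
tolerance 1e-10) and predicts the full class probability vector for each
query cell; the predicted label is the row argmax with lexicographic class
order breaking ties. Coordinates are centered on the reference before
fitting so that a global shift of the embedding cannot interact with the
penalty — shift invariance holds by construction. Probability rows sum to
one to within 1e-9 and are validated by the `TransferResult` class.

# The metric panel

All metrics return a raw score in [0, 1] with higher better. The selected
panel is: three Integration (Batch) metrics — batch principal-component
regression, the cell-specific mixing score (CMS) and iLISI; six
Integration (Bio) metrics — isolated label silhouette, isolated label F1,
batch-balanced NMI, cLISI, the local density factor difference and graph
connectivity; four mapping metrics — cell distance, label distance, mLISI
and qLISI; three classification metrics — F1 macro, micro and
rarity-weighted; and three unseen-population metrics — the Milo-style
neighbourhood score, unseen cell distance and unseen label distance. Graph
connectivity is scored in the Bio category: although historically framed as
a batch metric, it rewards coherent label neighbourhoods, which is a
biological-conservation property. Two further metrics are implemented but
excluded from category means by default: the kNN correlation (strongly
tied to the number of selected features) and the unseen uncertainty score
(dependent on classifier calibration); both can be opted in via the
category map.

Key definitions and the numerical choices behind them:

- **LISI family.** Per cell, Gaussian kernel weights over the 3x-perplexity
  nearest neighbours with the bandwidth solved so the weight entropy equals
  log(perplexity) (default perplexity 30); the inverse Simpson index of the
  grouping probabilities is averaged over cells and rescaled by the number
  of groups G: mixing modes map to (LISI-1)/(G-1), the label separation
  mode to (G-LISI)/(G-1). This is the distance-based, kernel-weighted
  variant: it is fully specified, and an independent brute-force
  implementation (dense distances, root-finding on the entropy equation)
  reproduces it to 1e-9 in the tests. Graph-based LISI variants found
  elsewhere will differ numerically.
- **Batch PCR.** PCs of the embedding are regressed on batch; R-squared
  values are averaged weighted by component variance. With a
  pre-integration embedding the score is the fraction of batch variance
  removed, clipped to [0, 1]; without one it falls back to one minus the
  post-integration value.
- **CMS.** Per reference cell, the distances to its 75 nearest neighbours
  are grouped by the neighbours' batch and compared with the k-sample
  Anderson-Darling test (the continuous Scholz-Stephens statistic with the
  published critical-value interpolation, implemented in-package and
  checked against an independent implementation); groups under 5 members
  are dropped and cells left with fewer than two groups score p = 0. The
  metric is 1 minus the fraction of cells with p < 0.1, so identically
  distributed batches sit near 0.9 — a calibration the test suite verifies.
- **Clustering-based metrics.** Leiden (modularity objective) on a
  90-nearest-neighbour graph, resolutions 0.1 to 2.0 in steps of 0.1, the
  resolution maximising the objective kept, ties to the lowest resolution.
  bNMI balances the contingency table with per-cell weights
  1/(B * n_batch(cell)) so every batch contributes equal total weight; with
  equal-size batches it reduces exactly to plain NMI, which is the tested
  anchor for the definition.
- **Isolated labels.** Labels present in the fewest batches. The silhouette
  variant averages rescaled silhouette widths (s+1)/2 of the label's own
  cells against the rest; the F1 variant takes, per isolated label, the
  best F1 between any Leiden cluster at any swept resolution and the label.
- **ldfDiff.** Per cell, the local density factor (kNN-kernel density over
  the mean density of its neighbours) is computed within the cell's own
  batch in the pre-integration space and in the full integrated space; the
  cell score is min(|log2 ratio|, u)/u with bound u = 1, and the metric is
  one minus the mean. The density estimate is the reciprocal mean
  neighbour distance — a deliberate simplification that is monotone in
  local density and exactly cancels in the identity case. The bound u is a
  package default, not an externally fixed constant.
- **Mahalanobis distances.** Label covariances are shrunk as
  Sigma + eps * (tr Sigma / d) * I with eps = 1e-6 (and a pseudo-inverse if
  still rank-deficient) so that small labels at d = 10-30 remain usable.
  The cell distance boundary is the type-7 (linear interpolation) 90th
  quantile of the reference's own distances, and "outside" is strict (>).
  A self-mapped query therefore scores very close to 0.90 by construction,
  which the suite asserts within 2/n. The label distance scales the
  centroid displacement by the maximum query-cell distance to the query
  centroid and skips labels with under 20 query cells. The mapping
  distances use ground-truth query labels, not transferred labels — they
  measure mapping geometry, while transfer quality is scored separately.
- **Milo-style unseen score.** Index cells are subsampled up to
  max(20,000, 10% of cells) using scores derived from hashed cell
  identifiers (so the subsample is invariant to row order); each index
  cell's k nearest neighbours form a neighbourhood with
  k = 5 x n_batches capped at 200. Per neighbourhood, batch-level member
  counts are tested for association with query status by negative binomial
  regression with a log batch-size offset; a regression that fails —
  including the complete-separation case where one side has no members and
  the Wald error explodes — falls back to an exact one-sided binomial test
  of query membership against the overall query fraction. P-values are
  Benjamini-Hochberg adjusted, neighbourhoods are attributed to their
  majority member label (ties to the index cell's label), and each unseen
  label scores the fraction of its neighbourhoods significant at FDR 0.1,
  zero if it owns none. With batch-level counts there are only a handful of
  observations per regression, so the binomial fallback carries much of the
  inference at desk scale; the null calibration and enrichment behaviour of
  the combined engine are what the acceptance tests pin down.
- **Classification.** Standard confusion-matrix scores on query cells whose
  true label exists in the reference; unseen cells are excluded because no
  correct answer exists for them. Rarity weighting uses weights
  proportional to 1/n_l over true query counts — favouring rare classes —
  normalised to sum to one. MCC is rescaled to [0, 1]; AUPRC is the
  macro-averaged one-vs-rest average precision over the probability
  columns.

# Scaling, aggregation and ranking

Raw metric values are not comparable across metrics or datasets: each has
its own effective range. Four baseline feature sets anchor that range per
(dataset, metric): all features; 2,000 batch-aware binned-dispersion HVGs;
500 random features averaged over five seeds; and 200 lowest-variance
features as the stable negative control (external baseline score tables can
be supplied instead — the scaling contract only needs a diverse baseline
set). Scores are scaled linearly so the minimum baseline maps to 0 and the
maximum to 1; values outside [0, 1] are preserved, not clipped, because a
method beating (or trailing) every baseline is exactly the information a
reader wants. Scaled scores are averaged per category, and the overall
score is the weighted mean

$$\mathrm{Overall} = \tfrac12\left(\tfrac{\mathrm{Int.Batch}}{2} +
\tfrac{\mathrm{Int.Bio}}{2}\right) + \tfrac12\left(
\tfrac{\mathrm{Mapping}}{3} + \tfrac{\mathrm{Class.}}{3} +
\tfrac{\mathrm{Unseen}}{3}\right)$$

— equal importance to building the reference and using it, and equal
weights within each side. Scaled scores are averaged unclipped. Ranking is
descending within each dataset at each level with average ranks for ties;
cross-dataset ranks are means of per-dataset ranks with their standard
deviation (sample, n-1, as everywhere in the package).
`standardizeScores()` provides the per-(dataset, method) z-scores used when
comparing sweeps such as the number of selected features, with constant
groups mapping to zero. `profileMetrics()` implements the metric-profiling
step: observed score ranges over random feature sets, correlation with the
number of features over ordered (ranked) sets, correlations with technical
dataset factors, and the full inter-metric correlation matrix — the
evidence needed to drop metrics that cannot distinguish feature sets or
that duplicate one another.

# Problem sizes and determinism

The test-suite and acceptance-script problem sizes are chosen as the
package's own desk-scale operating points: the default simulated scenario
(~2,000 cells, 1,000 features, six batches), calibration checks at 1,000
cells, and Milo constructions at 2,000 cells over ten seeds. Every
stochastic step — simulation, random selectors, Leiden initialisation,
index-cell subsampling — derives from explicit seeds, and the benchmark
orchestrator threads one master seed through all stages; a rerun with the
same seed reproduces every score table byte for byte, which is itself one
of the acceptance tests.

# Known limitations

The LISI implementation is the kernel-weighted distance-based variant, not
the graph-based one, so absolute values differ from graph-based pipelines
even though orientation and ordering agree. The Anderson-Darling p-values
are asymptotic and interpolated from the published critical table; they are
exact enough at the 0.1 decision threshold the CMS uses, but not in the
extreme tails. The Milo engine uses batch-level counts with few
observations, so its NB regression frequently defers to the exact binomial
fallback; it preserves the contract (fraction of FDR-significant
query-associated neighbourhoods) rather than any specific upstream
implementation. The simulator's unseen populations are generated as
distinct expression states; an unseen population that is a subtle shift of
a seen one will be harder for every unseen metric, and that regime is not
covered by the bundled scenario. Finally, silhouette-based scores compute a
dense distance matrix and are intended for references up to a few tens of
thousands of cells — subsample first beyond that.
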