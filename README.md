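# scMapBench

Benchmarking metrics for single-cell RNA-seq reference integration and
query-to-reference mapping.

Building a cell atlas means integrating multi-batch count data into one
embedding, mapping held-out query batches into it, transferring labels to
the query, and recognising query populations the reference has never seen.
scMapBench is the evaluation layer for that workflow, aimed at method
developers and atlas builders who need to compare feature selection or
integration choices on equal footing. It provides:

- a data model (`CellMatrix`, `SplitDataset`, `JointEmbedding`,
  `TransferResult`) with H5AD and TSV I/O and the standard preprocessing /
  reference-query split procedure (cell QC at 100 counts / 100 features,
  20-cell label filter per half, unseen labels removed from the reference,
  reference-unexpressed features dropped);
- a splat-style negative binomial simulator with batches, a two-branch
  trajectory, label-specific extra noise and designated query-only (unseen)
  populations, plus a fixture integrator with a tunable residual batch
  effect — so every stage is testable against known ground truth;
- simple and supervised feature selectors (all / random / high mean / high
  variance / binned-dispersion HVG / VST-style HVG, batch-aware
  combination, Wilcoxon marker cascade);
- multinomial logistic regression label transfer;
- the selected metric panel — Batch PCR, CMS, iLISI (batch); isolated label
  ASW and F1, bNMI, cLISI, ldfDiff, graph connectivity (bio); cell and
  label Mahalanobis distances, mLISI, qLISI (mapping); F1 macro / micro /
  rarity (classification); Milo-style neighbourhood enrichment, unseen cell
  and label distances (unseen populations) — every score in [0, 1], higher
  better;
- baseline-anchored scaling, category means, the weighted overall score,
  rankings, z-score standardisation and metric profiling.

The overall score weights integration and query use equally:

```
Overall = 1/2 (Int.Batch/2 + Int.Bio/2) + 1/2 (Mapping/3 + Class./3 + Unseen/3)
```

Raw metric scores are first rescaled per dataset against four baseline
feature sets (all features, batch-aware HVGs, random sets averaged over
five seeds, and a stable lowest-variance negative control):
`scaled = (raw - min_baseline) / (max_baseline - min_baseline)`, with
values outside [0, 1] kept — a method can beat or trail every baseline.

## Worked example

Simulate the bundled multi-technology scenario, select features, integrate
with the fixture integrator, transfer labels and score everything:

```r
library(scMapBench)

ds <- simulateCounts(simConfig(nFeatures = 300, seed = 1))
ds
#> SplitDataset
#>   reference: 900 cells, 4 batches, 7 labels
#>   query:     1110 cells, 2 batches, 10 labels
#>   features:  300
#>   unseen:    Rare, Perturbed, Intermediate

sel <- selectFeatures(reference(ds), "hvg_vst", n = 150)
emb <- fixtureIntegrate(ds, nPcs = 10, removal = 0.75,
                        features = sel$features)
tr  <- transferLabels(emb, cellLabel(reference(ds)))
tab <- computeMetrics(ds, emb, tr, cfg = metricConfig(seed = 1),
                      dataset = "splat_demo", method = "hvg_vst")
tab[, c("metric", "category", "value")]
#>                   metric       category value
#> 1              batch_pcr          batch  0.93
#> 2                    cms          batch  0.86
#> 3                  ilisi          batch  0.72
#> 4     isolated_label_asw            bio  0.55
#> 5      isolated_label_f1            bio  0.48
#> 6                   bnmi            bio  0.32
#> 7                  clisi            bio  0.59
#> 8               ldf_diff            bio  0.91
#> 9     graph_connectivity            bio  1.00
#> 10         cell_distance        mapping  0.51
#> 11        label_distance        mapping  0.82
#> 12                 mlisi        mapping  0.65
#> 13                 qlisi        mapping  0.88
#> 14              f1_macro classification  0.32
#> 15              f1_micro classification  0.43
#> 16             f1_rarity classification  0.29
#> 17                  milo         unseen  0.57
#> 18  unseen_cell_distance         unseen  0.33
#> 19 unseen_label_distance         unseen  0.19
```

Reading the panel: the fixture integrator at `removal = 0.75` leaves a
small residual batch effect, so the batch metrics sit high but below 1
(batch PCR 0.93 means 93% of the batch variance present before integration
was removed; CMS 0.86 means 14% of cells still detect locally distinguishable
batches at p < 0.1). The mapping scores say shared-label query cells land
reasonably inside their reference populations (cell distance 0.51 against
a 0.90 self-map ideal), classification is modest at this feature count and
depth, and the unseen scores show the query-only populations are only
partially separable in this embedding.

`runBenchmark()` chains all of this over a method list plus the four
baselines, scales, aggregates and ranks:

```r
res <- runBenchmark(simCfg = simConfig(seed = 1), seed = 1)
res$summary   # per-method category means + overall
res$ranks     # per-dataset and cross-dataset rankings
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/scmapbench` (subcommands `simulate`, `run`, `metrics`,
`score`) for H5AD-file workflows.

## Vignette

`vignettes/benchmarking-integration-metrics.Rmd` documents the data model,
the simulator and what it does and does not emulate, each metric's
definition with its parameters and numerical conventions, the
scaling/aggregation scheme, and known limitations.
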