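# pathstrat

Sequential pathway expression-pattern survival stratification for tumor
cohorts.

## The problem

Long-term survival in many cancers tracks the *relative expression pattern*
of small sets of functionally related transcripts — a pathway's members are
co-regulated, and the shape of their joint expression reports on the tumor's
regulatory state better than any single transcript's level. `pathstrat`
turns that observation into a reusable pipeline for anyone with a
gene-by-sample expression matrix (e.g. TCGA-style FPKM-UQ), a clinical
survival table, and pathway gene sets in GMT format:

1. restrict the matrix to one pathway's transcripts;
2. normalize each sample's pathway vector to sum 1 and project it onto the
   unit hypersphere, so only the pattern — not the magnitude — remains
   (for non-negative data the composition equals direct L2 normalization);
3. embed the vectors with exact t-SNE (2-D or 3-D, seeded);
4. delineate clusters with a Gaussian mixture model — component count by
   BIC scan, components merged into clusters by posterior overlap, or a
   fixed `k`;
5. compare the clusters' survival: Kaplan-Meier curves
   \(\hat S(t) = \prod_{t_j \le t}(1 - d_j/n_j)\), medians with explicit
   `"> M days"` not-reached semantics, overall and pairwise log-rank tests
   (observed vs expected events with the hypergeometric variance), and
   Fisher's exact test for cluster-group associations.

The package's namesake step is **sequential stratification**: re-running the
entire pipeline with a *second* pathway inside a chosen first-pass cluster
(`sequential_stratify()`), or inside groups cut from a whole-transcriptome
dendrogram (`hclust_dendro()` + `dendro_stratify()`), to split survival
groups further than any single analysis can. A seeded synthetic-cohort
generator with planted cluster structure and cluster-dependent exponential
survival (`simulate_cohort()`, `reference_specs()`) makes every stage
testable without downloading anything.

## Worked example

A synthetic 600-tumor cohort in which pathway PWA splits the cohort into a
favorable and an unfavorable prognosis cluster (hazard ratio 2), and a
second pathway PWB further splits the favorable cluster (hazard ratio 2):

```r
library(pathstrat)

spec     <- reference_specs()[["nested-HR2"]]
cohort   <- simulate_cohort(spec)            # expression + clinical + truth
pathways <- synthetic_pathways(spec)

first <- stratify(cohort$expression, cohort$clinical, pathways$PWA, seed = 1)
first
#> Pathway survival stratification ('PWA'): 600 samples, k = 2 clusters
#>   cluster 1: n = 312, median survival 2468.531 days
#>   cluster 2: n = 288, median survival 1571.813 days
#>   overall log-rank: chi-square = 16.29 (1 df), p = 5.423e-05

second <- sequential_stratify(first, 1L, cohort$expression, cohort$clinical,
                              pathways$PWB, seed = 1)
second
#> Pathway survival stratification ('PWB'): 312 samples, k = 2 clusters
#>   cluster 1: n = 169, median survival 2066.049 days
#>   cluster 2: n = 143, median survival 3380.241 days
#>   overall log-rank: chi-square = 16.23 (1 df), p = 5.62e-05
```

The first pass finds the planted two-cluster pattern split and its survival
difference (2469 vs 1572 days). Re-analyzing only the 312 favorable-cluster
tumors with the second pathway reveals the hidden sub-split (3380 vs 2066
days, p = 5.6e-05) — invisible to any single-pathway analysis of the whole
cohort, because PWB's hazard effect exists only inside PWA's favorable
cluster. The between-extreme median gap grows from 897 days (single pass)
to 1808 days (sequential), and the recovered sub-clusters match the planted
labels exactly (adjusted Rand index 1.0). `plot(first, "km")` and
`plot(first, "embedding")` draw the annotated survival curves and the
colored embedding; `summary(second)` adds pairwise tests, the BIC table and
the provenance chain.

Command-line use mirrors the R interface via a YAML config
(`inst/cli/pathstrat.R` with subcommands `simulate`, `stratify`,
`sequential`, `dendro`; see `cmd_stratify()` / `cmd_sequential()`), writing
a report directory of TSV tables plus a `provenance.json` that reproduces
the run byte-for-byte.

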