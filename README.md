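# pannetomics

Multi-omic subtype discovery for pancreatic neuroendocrine tumors (PanNETs)
with *MEN1*/*DAXX*/*ATRX* loss of function, as a tested, reusable R pipeline.

## The problem

PanNETs carrying mutations in *MEN1*, *DAXX* and *ATRX* are the largest
genomic PanNET group, yet they are biologically heterogeneous: tumors with
combined loss (ADM) are chromosomally unstable, activate alternative
lengthening of telomeres (ALT), and split further into transcriptomic
subtypes with distinct programs (hypoxia/glycolysis, immune infiltration, or
no special type). Dissecting this heterogeneity takes a two-level multi-omic
analysis:

1. **Methylation level** — consensus clustering of DNA-methylation β values
   separates α-like tumors (*MEN1* loss only, α-cell-like epigenome) from
   ADM tumors; differential methylation then characterizes the ADM
   epigenome, including hypomethylation of sub-telomeric and
   peri-centromeric heterochromatin that plausibly links DAXX/ATRX loss to
   ALT and chromosomal instability.
2. **Expression level** — within ADM tumors, consensus clustering of
   RNA-seq profiles defines transcriptomic subtypes; one-vs-rest
   differential expression, gene-set enrichment and rank-sum signature
   scores characterize each; and a promoter-methylation ↔ expression
   anti-correlation screen asks which subtype programs are epigenetically
   driven.

`pannetomics` implements this workflow end to end, together with a
synthetic-cohort generator that plants every effect the pipeline is designed
to detect — so the whole analysis can be validated by parameter recovery
against a known ground truth.

## The methods at the core

- **Consensus clustering** (Monti-style): for each of `reps = 1000`
  resampling runs, `pItem = 0.8` of the samples are drawn without
  replacement and clustered hierarchically on the Pearson dissimilarity
  `d(i,j) = 1 − cor(x_i, x_j)` with ward.D2 inner linkage. The consensus
  matrix entry `M[i,j]` is the fraction of co-sampled runs in which *i* and
  *j* co-cluster; final assignments cut an average-linkage tree on `1 − M`.
  Model selection uses the area under the consensus CDF and its relative
  change Δ(k) across k.
- **Differential methylation**: per-probe OLS of β on the group indicator,
  two-sided t test, Benjamini–Hochberg adjustment; DMPs at
  `p.adj < 0.001, |Δβ| > 0.2`. Chromatin-state enrichment of DMPs by
  one-sided Fisher exact test (hypergeometric upper tail). Structural-region
  statistics: per-sample median β over sub-telomeric / peri-centromeric
  windows (2 Mb defaults), compared between groups by Welch's t test.
- **Differential expression**: low-count filter (≥ 2 samples with ≥ 5
  reads), median-of-ratios size factors, NB log-linear model with trend-
  shrunk method-of-moments dispersion and a Wald test, one subtype vs the
  rest; DEGs at `|log2FC| > 1, p.adj < 0.05`.
- **Integration screen**: Spearman correlation between promoter-probe
  M-values `M = log2(β/(1−β))` and expression for every (DEG, promoter
  probe) pair; candidates pass at `ρ < −0.6` and BH `p.adj < 0.05`. Exact
  permutation p-values for small n, t approximation otherwise.
- **Signatures & enrichment**: per-sample sum of gene-wise across-sample
  ranks (MLP1-style score); preranked GSEA with gene-label permutation;
  gene-set over-representation via the shared Fisher engine.
- **Survival & associations**: Kaplan–Meier / log-rank disease-free
  survival across subtypes; Pearson χ² with simulated p-value (fixed-margin
  Monte Carlo) for subtype–tumor-size association.

## Worked example

```r
library(pannetomics)

cohort <- simulate_cohort(seed = 1)   # 90 samples, 10k probes, 5k genes
res <- run_pipeline(cohort, "run1", pipeline_config(reps = 250, seed = 2),
                    signature_genes = cohort$truth$signature_genes)

table(res$methylation$labels)
#>        ADM alpha_like
#>         60         30
```

The methylation level recovers the planted α-like/ADM split exactly (the
cluster with more DAXX/ATRX-lost samples is named ADM). Differential
methylation finds `507` DMPs (500 planted), enriched where planted:

```r
res$methylation$region_tests
#>      region_class  mean_diff t_statistic       p_value
#> 1 pericentromeric -0.1496906   -350.5342 5.868102e-138
#> 2    subtelomeric -0.1510708   -298.8653 4.330522e-106

head(res$methylation$state_ora[order(res$methylation$state_ora$p_value), ], 2)
#>           category odds_ratio p_adjusted
#> 2         enhancer       2.93   2.58e-27
#> 4 lowly_methylated       2.08   1.56e-10
```

The planted −0.15 β shift in ADM structural regions is estimated at
−0.150/−0.151, and the enhancer bias of the planted DMP block shows up as an
odds ratio of 2.9. At the expression level the four planted transcriptomic
subtypes are recovered (the 2-sample ADM4 cluster is excluded from testing,
as clusters below `min_cluster_size = 3` always are), with 403/436/406
DEGs for the three usable subtypes, and the integration screen flags

```r
attr(res$expression$associations$ADM1, "summary")
#>   up down
#>   40    0
```

40 up-regulated genes anti-correlated with their promoter methylation in the
hypoxia-like subtype — exactly the planted coupled set.

## Command line

```sh
Rscript inst/cli/pannet.R simulate --out cohort_dir --seed 1
Rscript inst/cli/pannet.R run --in cohort_dir --out run_dir --seed 1 [--config cfg.yaml]
Rscript inst/cli/pannet.R report --in run_dir
```

The YAML config holds overrides for `pipeline_config()` /
`simulate_cohort()` fields; every run directory contains all tabular results
plus a `provenance.json` with the config, seed and input hashes. Two runs
with the same inputs, config and seed are byte-identical.

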