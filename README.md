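# hsccycle

Single-cell RNA-seq analysis of the hematopoietic stem cell (HSC)
compartment, built around ERCC spike-in calibration: cell-level quality
control, size-factor normalization, detection of highly variable genes
against a spike-in technical-noise model, transcriptomic reconstruction of
cell-cycle progression with projection of a perturbed (knockout)
population, dissection of lineage-primed subpopulations, and from-scratch
gene-set enrichment statistics. A seeded synthetic-data generator plants
known stage, lineage and genotype structure, so the entire pipeline is
testable against ground truth without any sequencing data.

## Who it is for

Analysts working with plate/microfluidic scRNA-seq of rare sorted
populations (~100–200 cells per group, deep coverage, ERCC spike-ins) who
want a reproducible, tested reimplementation of this classic analysis
stack — or a simulation harness to study its operating characteristics.

## The statistics at its core

**Technical noise and variable genes.** Across cells, the squared
coefficient of variation of spike-in species follows

```
CV²_tech(μ) = a1/μ + α0
```

fitted by a gamma GLM with identity link on the spike-in (μ, CV²) pairs.
A gene with normalized mean μᵢ and variance vᵢ over m cells is tested
against technical noise plus a minimal biological dispersion
(`min_biol_cv = 0.5`, i.e. 50% biological CV) with the statistic

```
T_i = (m−1) vᵢ / dᵢ ,   dᵢ = (μᵢψ + μᵢ²c) / (1 + c/minBiolDisp)
```

where `c = α0 + minBiolDisp + α0·minBiolDisp`, ψ translates the fitted
shot-noise coefficient onto the biological size-factor scale, and `Tᵢ` is
referred to χ²(m−1); genes with Benjamini–Hochberg adjusted p < 0.1 are
called highly variable.

**Cell-cycle staging.** PCA of `log2(normalized + 1)` expression over a
curated cell-cycle gene list; k-means clusters (C1–C5) in PC1/PC2;
clusters labelled G0/early-G1, late-G1, S or G2/M by marker-panel z-scores
(Cdkn1c/Txnip high + Uhrf1 low → quiescent; Rrm2/Mcm/Ccna2 → S;
Ccnb2/Cdk1/Prc1/Plk1/Mki67 → G2/M). Knockout cells are projected onto the
reference embedding and inherit the nearest centroid's stage; occupancy
shifts are tested with Fisher's exact test and per-cell transcriptional
activity (total counts / ERCC size factor) with Wilcoxon rank-sum tests.

**Enrichment.** GSEA as the weighted Kolmogorov–Smirnov running-sum
statistic on a signal-to-noise ranking, with phenotype permutation for
nominal p, NES and a pooled-NES FDR; over-representation as the upper-tail
hypergeometric test with BH adjustment.

## Worked example

```r
library(hsccycle)

sim  <- simulate_experiment(sim_config(n_cells = c(WT = 119, KO = 61), seed = 1))
sf   <- size_factors(sim$counts)
norm <- normalize_counts(sim$counts, sf)

grp <- setNames(sim$metadata$group, sim$metadata$cell_id)
wt  <- names(grp)[grp == "WT"]; ko <- names(grp)[grp == "KO"]

emb   <- pca_embed(norm[, wt], sim$sets$cell_cycle)
cl    <- cluster_embedding(emb, k = 5, seed = 1)
model <- assign_cluster_stages(emb, cl, norm[, wt], groups = grp)
koasg <- project_and_classify(emb, model, norm[, ko], groups = grp)

compare_occupancy(koasg, model$assignment, c("S", "G2/M"))
```

```
# A tibble: 1 × 10
  stages frac_a frac_b difference  in_a   n_a  in_b   n_b p_value odds_ratio
  <chr>   <dbl>  <dbl>      <dbl> <int> <int> <int> <int>   <dbl>      <dbl>
1 S+G2/M  0.541  0.294      0.247    33    61    35   119 0.00190       2.81
```

Read: 54.1% of the simulated knockout cells fall in the proliferative
S/G2-M space versus 29.4% of controls (the generator plants 59% vs ~26.5%;
the realized draw varies with n), a shift Fisher's exact test calls highly
significant. `autoplot(model$assignment)` draws the staged embedding, and
`gsea(norm[!sim$counts$is_spikein, ], grp[colnames(norm)], sim$sets["lymphoid_signature"])`
recovers the planted depletion of the lymphoid signature in the knockout.

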