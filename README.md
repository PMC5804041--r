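# mirCoNet

Integrative miRNA–mRNA co-expression network analysis for two-group
designs, built for studies that contrast animals (or any samples) with
extreme genetic merit for a quantitative trait — the motivating case being
intramuscular fat (IMF) deposition in beef-cattle skeletal muscle, where 15
steers with high and 15 with low genomic estimated breeding values (GEBV)
for IMF are profiled on both the miRNA and mRNA layer.

The package is aimed at systems-biology practitioners who want the whole
chain — normalization, differential expression, condition-specific
networks, regulator ranking, module detection, cross-layer integration,
targeting and enrichment — as composable, tested R functions rather than a
collection of one-off scripts.

## What it computes

Given feature × sample count tables for the two layers and a per-sample
phenotype table, the package provides:

* **Normalization and differential expression.** Median-of-ratios size
  factors s_j; log2(count/s_j + 1) expression; a per-feature
  negative-binomial log-linear model `count ~ group + covariates` with a
  log s_j offset, fit by IRLS with a moments dispersion (Var = μ + αμ²)
  and a quasi-likelihood guarded Wald test on the group coefficient;
  Benjamini–Hochberg FDR at 10%. Fold changes are oriented Low vs High:
  negative values mean lower expression in the Low group.
* **PCIT networks and differential hubbing (DH).** Per-group Pearson
  correlation networks over the combined miRNA+mRNA feature list, filtered
  by the partial-correlation-with-information-theory rule: for every trio
  (x,y,z) the first-order partials r_xy·z = (r_xy − r_xz r_yz) / √((1 −
  r_xz²)(1 − r_yz²)) define a trio tolerance ε (mean of partial/direct
  ratios), and the pair (x,y) is dropped when |r_xy| < |ε r_xz| and
  |r_xy| < |ε r_yz| for some z. A connection is a retained edge with
  |r| > 0.9; DH = conn_H − conn_L (negative ⇒ more wired in Low).
* **PIF / RIF regulator ranking.** PIF_j = ā_j·d_j (average abundance ×
  expression contrast); RIF1_i = mean_j PIF_j (r_H,ij − r_L,ij)²
  (differential wiring to the DE features); RIF2_i = mean_j [(μ_H,j
  r_H,ij)² − (μ_L,j r_L,ij)²] (change in predicted ability), raw and
  z-standardized.
* **Signed co-expression modules.** Signed similarity (1 + r)/2 raised to
  the lowest power β with scale-free fit R² > 0.90; topological overlap
  TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 − a_ij);
  average-linkage clustering with a static cut, minimum module sizes 30
  (mRNA) / 5 (miRNA), eigengenes (first principal component), merging of
  modules whose eigengenes correlate above 0.75, module membership and hub
  calls.
* **Integration.** miRNA-module × mRNA-module eigengene correlations
  (retained at r ≤ −0.4, p < 0.05), module–trait correlations (retained at
  p < 0.1), and hub-miRNA ↔ enriched-term bipartite graphs.
* **Targets and enrichment.** Canonical seed sites (8mer, 7mer-m8,
  7mer-A1) of miRNA positions 2–8 scanned against 3'UTR FASTA, and
  upper-tail hypergeometric gene-set enrichment with BH control.
* **A synthetic-data generator with planted truth** (modules, DE, a
  differentially wired regulator, a group-specific hub, a module-driven
  trait) plus `evaluateRecovery()` for end-to-end recovery testing.

## Worked example

```r
library(mirCoNet)

ph <- readPhenotypes(system.file("extdata", "imf_gebv_phenotypes.tsv",
                                 package = "mirCoNet"))
summarizePhenotypes(ph, "imf_percent")
#>   group  n     mean        sd mean_rounded sd_flag
#> 1     H 15 4.306667 0.5607605        4.307   FALSE
#> 2     L 15 1.508000 0.3547474        1.508   FALSE
compareGroups(ph, "gebv")$p.value
#> [1] 5.636501e-17
```

The High group averages 4.31% IMF against 1.51% in the Low group, and the
Welch test confirms the GEBV separation of the two groups is overwhelming
(p ≈ 6e-17).

```r
ds <- generateDataset(simConfig(seed = 1))   # 2,000 genes, 150 miRNAs, 15+15
de <- deTest(ds$mirna, ds$phenotypes,
             covariates = c("age_days", "contemporary_group"))
head(de[de$de, c("feature", "log2FoldChange", "qvalue")])
#>      feature log2FoldChange       qvalue
#> 46  mir_0046      2.5285015 0.0001002720
#> 47  mir_0047      1.8142179 0.0012681710
#> 48  mir_0048      1.6991599 0.0007237231
#> 49  mir_0049      2.1569552 0.0001002720
#> 50  mir_0050      1.5954596 0.0030280248
#> 51  mir_0051      1.7718088 0.0002602221
```

The six strongly DE miRNAs planted inside the co-regulated module
(mir_0046–mir_0051, true log2FC 1.30–1.71, higher in the Low group) are
all flagged at FDR 10% with the right orientation.

```r
ms <- coexpressionModules(normalizeCounts(ds$mrna), minSize = 30)
mt <- moduleTraitCorrelation(ms, ds$phenotypes, trait = "imf_percent")
head(mt[order(-abs(mt$r)), ], 2)
#>   module       trait          r            p retained
#> 1   blue imf_percent  0.8193270 3.086351e-08     TRUE
#> 3  green imf_percent -0.3477012 5.973556e-02     TRUE

msM <- coexpressionModules(normalizeCounts(ds$mirna), minSize = 5)
mm  <- moduleModuleCorrelation(msM, ms)
mm[mm$retained, ]
#>    mirnaModule mrnaModule          r            p retained
#> 70   turquoise        red -0.4538338 1.176777e-02     TRUE
#> 74      yellow      brown -0.9781554 1.207520e-20     TRUE
```

The blue mRNA module is the planted trait driver (r = 0.82 with IMF), and
the yellow-miRNA / brown-mRNA pair (r = −0.98) is the planted
anti-correlated cross-layer pair.

`runPipeline(outDir, simConfig(seed = 1))` chains all stages end-to-end
and writes deterministic TSV outputs plus a report; see the methods
vignette (`vignettes/integrative-coexpression.Rmd`) for the model details
and design decisions.

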