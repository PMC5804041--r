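---
title: "Integrative miRNA-mRNA co-expression analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative miRNA-mRNA co-expression analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirCoNet)
```

# Scope

mirCoNet analyses paired microRNA and mRNA count data from a two-group
design — typically samples selected for extreme genomic breeding values of
a quantitative trait such as intramuscular fat percentage (IMF) — and asks
three questions: which miRNAs respond to the group contrast, which
features rewire their co-expression between the groups (candidate
regulators), and which co-expression modules on either layer track each
other and the trait. This vignette documents the models, the tunable
parameters, the synthetic data the test suite relies on, and the design
decisions that were genuinely open.

# Normalization and differential expression

Counts are normalized with median-of-ratios size factors: for features
with positive counts in every sample, each sample's factor is the median
ratio of its counts to the feature-wise geometric mean, rescaled to
geometric mean 1. Expression is `log2(count / s_j + pseudocount)` with a
pseudocount of 1 (keeping zeros finite at the cost of compressing
fold changes of low-abundance features; all network and module stages
operate on this scale, so the compression is shared by every downstream
statistic).

The DE stage fits, per feature, a negative-binomial log-linear model
`count ~ group + covariates` with `log s_j` as offset, NB variance
`mu + alpha * mu^2`. It is intentionally simple:

* the dispersion `alpha` is a moments estimator from the Poisson-fit
  residuals, with the residual degrees-of-freedom correction `n / (n - p)`
  on the squared residuals — no shrinkage across features;
* the group coefficient (coded Low minus High, so negative log2 fold
  changes mean lower expression in the Low group) is tested with a Wald
  statistic referenced to a t distribution on `n - p` degrees of freedom;
* the standard error is inflated by the square root of the Pearson
  chi-square over residual df on the NB working variance, floored at 1.
  This quasi-likelihood guard matters for family-wise behaviour: with
  n = 30 a per-feature moments dispersion is occasionally under-estimated,
  and without the guard the extreme tail of the p-value distribution is
  anti-conservative enough that Benjamini-Hochberg selection at 10% over
  a few hundred null features rejects too often. With it, the null
  type-I error at 0.05 sits near 0.04-0.06 and the empirical
  false-discovery proportion of BH at 10% stays at or below its nominal
  level (both are measured by the acceptance suite).

Features that are all-zero or constant are reported as untestable with
p = 1 and log2FC = 0; non-converged fits are flagged and given p = 1.
Categorical covariates enter as one-hot fixed effects, with a warning when
a level occurs in only one group (confounding). There is no outlier
replacement and no independent filtering; exact fold-change values from
shrinkage-based tools are therefore not comparable to this stage's
estimates.

# PCIT and differential hubbing

Per group, Pearson correlations of the log-normalized expression are
computed over the combined miRNA + mRNA feature list (constant features
dropped with a warning; two-sided p-values from the t transform on n - 2
df). The PCIT filter then examines every feature trio (x, y, z): with
first-order partial correlations

r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)) (and cyclic),

the trio tolerance is the mean of the signed partial/direct ratios,
eps = (r_xy.z/r_xy + r_xz.y/r_xz + r_yz.x/r_yz) / 3, and the pair (x, y)
is eliminated when |r_xy| < |eps r_xz| and |r_xy| < |eps r_yz| for some z.
Trios in which a ratio is undefined (a correlation numerically 0) or a
partial-correlation denominator underflows (|r| >= 1 - 1e-12) are skipped
and counted. With fewer than three features every pair is retained by
convention.

Two implementations exist: a compiled O(n^3) kernel (`pcit`) used in
production and a deliberately plain R triple loop (`pcitReference`) that
serves as the definition of record; the test and acceptance suites assert
exact equality of the two on random instances. Note that the trio rule is
a *relative* filter: it prunes the weakest association within
well-connected trios but is not, by itself, a significance filter — in
particular, a spurious near-zero edge between independent features is
only removed when some control feature produces a sufficiently large
tolerance, which simulation shows happens for a minority of seeds. The
biological edge set is therefore always the intersection of PCIT
retention with the |r| > 0.9 connection filter.

A connection in group g is a PCIT-retained pair with |r_g| above the edge
threshold (default 0.9, applied to the absolute correlation — negative
edges count and keep their sign in exports). Differential hubbing is
DH = conn_H - conn_L per feature; negative DH means more connections in
the Low group. `topDh` returns the ten most positive and most negative
features (lexicographic tie-break), and `hubNeighbors` extracts each
hub's partners with signed edges for downstream enrichment and export.

Because PCIT is cubic in the feature count, network stages default to a
variance-based pre-filter of the top 500 features (`topVarianceFeatures`);
the cap is a plain argument and can be disabled. The moderate scale keeps
a full two-group analysis under a minute on one core; a transcriptome-wide
15,000-feature run is cluster-scale and out of the package's default path.

# PIF and RIF

With per-group means of log2-normalized expression mu_H and mu_L,
abundance a = (mu_H + mu_L)/2 and contrast d = mu_H - mu_L, the
phenotypic impact factor is PIF_j = a_j d_j. For a candidate regulator i
and the set of DE features j:

* RIF1_i = mean_j PIF_j (r_H,ij - r_L,ij)^2 — PIF-weighted differential
  wiring;
* RIF2_i = mean_j [(mu_H,j r_H,ij)^2 - (mu_L,j r_L,ij)^2] — change in the
  regulator's squared ability to predict the DE features.

These closed forms are the package's definition of record, checked
against independent scalar loops in the tests. Both raw and standardized
(mean 0, sd 1 over scored regulators) scores are returned, since ranking
conventions differ between studies; rankings by z-score are invariant to
affine rescaling of the raw scores. Candidate regulators default to all
features; the DE set defaults to the DE stage's FDR <= 10% flags and can
be overridden with an explicit list (the recovery suite does so with the
planted truth, separating regulator-ranking behaviour from DE power).

# Signed co-expression modules

Per layer (and per group in the pipeline), the signed similarity
s = (1 + r)/2 is raised to a soft-threshold power beta to give the
adjacency a = s^beta. beta is the lowest integer in 1..20 whose
connectivity distribution passes a scale-free fit with signed R^2 > 0.90;
if none qualifies the best-fitting power is used with a warning. The fit
bins connectivity into 10 equal-occupancy bins and regresses log10 of the
*frequency density* (bin share divided by bin width) on log10 of the bin
mean — with quantile bins the raw bin share is constant by construction,
so the density is the meaningful estimate of p(k). The R^2 is negated
when the slope is positive.

The topological overlap TOM_ij = (sum_u a_iu a_uj + a_ij) /
(min(k_i, k_j) + 1 - a_ij) (diagonal 1) gives the clustering
dissimilarity 1 - TOM. Average-linkage hierarchical clustering is cut at
a single static height. The default cut is the 0.85 quantile of the
dendrogram merge heights: unstructured features coalesce in a narrow band
just below the dendrogram top, so a cut in the top few percent of heights
(we first considered 0.99) lands above that band and returns one giant
cluster, while the 0.85 quantile sits reliably below it across both layer
scales (150 and 2,000 features) in simulation. A static cut is simpler
and fully deterministic compared with dynamic tree cutting, at the cost
of less adaptivity on real dendrograms — the cut height is exposed as a
parameter for that reason.

Clusters smaller than the minimum size (defaults 30 for mRNA, 5 for
miRNA, reflecting the much smaller miRNA transcriptome) are assigned to
the grey (unassigned) pool. Module eigengenes are the first right
singular vector of the row-standardized module submatrix, signed so the
mean correlation with members is positive; zero-variance members are
dropped with a warning, and the variance explained is the top singular
value's share. Modules whose eigengene dissimilarity 1 - cor falls below
the merge height (default 0.25) are merged iteratively, closest pair
first. Final modules are renamed by decreasing size along the familiar
colour palette; colours carry no meaning. Module membership is the
feature-eigengene correlation, and each module's hub is its
maximal-membership member (lexicographic tie-break).

# Integration

miRNA-module and mRNA-module eigengenes over the same samples are
correlated pairwise; a pair is retained when r <= -0.4 with p < 0.05
(negative correlation consistent with miRNA-mediated repression).
Module-trait correlations use the same t transform with a deliberately
permissive unadjusted p < 0.1 — the stage is exploratory and feeds manual
inspection, so multiplicity control is left to the user. IMF percent is
the default trait column; a parameter switches to GEBV or any numeric
column. `bipartiteNetwork` links each retained pair's hub miRNAs to the
enriched terms of the partner mRNA module, giving the familiar
hub-to-process bipartite graph for export as GraphML.

# Targets and enrichment

Canonical seed matching stands in for full alignment-based target
predictors: the seed is miRNA positions 2-8 (5' to 3'), and the UTR
(sense strand, DNA alphabet; U and T are interchangeable on input) is
scanned for the 7mer-m8 site (reverse complement of the seed), the 8mer
(7mer-m8 followed by A) and the 7mer-A1 (reverse complement of positions
2-7 followed by A). All, including overlapping, occurrences are reported
with 0-based half-open coordinates. This reproduces only the
complementarity core of the usual tools — no context scores, conservation
or free-energy filtering — so its target sets are a superset-flavoured
approximation suitable for enrichment, not site-level prediction. Target
maps may be intersected with an expressed-gene filter; when multiple
predictors are combined upstream, the union is the default reading.

Enrichment is the upper-tail hypergeometric test P[X >= k] per annotation
term (members intersected with the declared universe; terms tested only
when 1 <= K <= N - 1 and k >= 1), with BH control across tested terms and
a flag at FDR 10%. miRNA-module enrichment tests the union of the
module's hub targets. The hypergeometric p is checked against exhaustive
enumeration for small universes in the tests.

# The synthetic data generator

`simConfig`/`generateDataset` emulate the study design end-to-end: two
groups of 15 samples, 2,000 genes and 150 miRNAs, NB counts with
alpha = 0.1 (typical bulk RNA-seq overdispersion), lognormal library-size
factors (sd 0.3 on the log scale), and baseline log2 abundances uniform
on 5-9. Counts are drawn as
NB(mean = s_j 2^(mu_i + loading_i F_m(i),j + de_i g_j), alpha) with one
standard-normal latent factor per module shared across its members; the
trait is baseline + slope F_driver + Gaussian noise, and GEBV is the
group contrast plus a scaled trait deviation with noise. A single
`set.seed` stream per dataset with a fixed generation order makes every
draw reproducible from the config seed (a counter-split stream was
considered and rejected as needless machinery given the fixed order).

The planted constructs and the reasoning behind their default strengths:

* **Plain modules** (M1, M2, M3, M4 on the mRNA layer, m1 and m2 on the
  miRNA layer) use loading 0.7, i.e. within-module correlation about
  0.5-0.6 — typical of real co-expression modules, and deliberately well
  below the 0.9 connection filter: with 15 samples per group the
  group-level spread of a module's latent factor varies enough that
  modules correlated near the threshold would cross it in one group by
  chance, turning threshold noise into spurious differential hubbing.
* **The cross-layer pair** shares one factor with loading +0.75 on a
  60-gene mRNA module and -0.9 on a 10-miRNA module. The small miRNA
  module needs the stronger loading to remain distinct from the
  background's shared normalization component when only 150 features are
  clustered; the resulting eigengene pair correlates near -0.95.
* **The tight module MT** (40 genes, loading 2.5, within-module r about
  0.97) exists to carry the differential-hubbing construct: the
  **planted hub** is wired to MT's factor with loading 2.5 in the Low
  group only, giving it about 40 Low-only connections — a margin no
  background feature reaches once plain modules sit safely below the
  filter.
* **Planted DE**: six miRNAs inside the co-regulated module mDE
  (loading 0.9) shift coherently upward in the Low group with log2FC
  1.30-1.71, plus four weak mixed-sign DE miRNAs (|log2FC| 0.4-0.6) among
  the background. Coherent in-module shifts are the biologically sensible
  default (co-module miRNAs move together) and are also what makes
  regulator ranking well-posed: RIF1 weights the wiring change by PIF,
  and mixed signs within one module cancel the weights of any regulator
  wired to that module as a whole.
* **The differentially wired regulator** couples to mDE's factor with
  loading +2.0 in High and -2.0 in Low — a sign-reversing rewiring with
  (r_H - r_L)^2 near 3.5. The sign flip is not cosmetic: with 15 samples
  per group the null differential-wiring noise against a module factor is
  heavy-tailed (essentially 0.14 times a chi-square with one degree of
  freedom, maximized over ~2,000 candidates, reaching ~1.9), while any
  one-sided wiring is bounded by (r_H)^2 < 1. Only a sign-reversing
  regulator clears the null tail reliably, so that is the construct the
  generator plants.

What the generator does *not* emulate: per-feature dispersion variation,
GC or length biases, batch structure beyond the contemporary-group label,
compositional effects, correlated noise between the layers, and genuine
miRNA-to-target causal repression (the cross-layer pair is a shared
latent factor with opposite signs, not a kinetic model). Passing recovery
tests therefore demonstrates that the algorithms recover the constructs
they are defined on at realistic noise levels — not that they are robust
to every artefact of real sequencing data.

# Recovery evaluation and problem sizes

`evaluateRecovery` generates one dataset and checks: the regulator
attains the top |RIF1 z| among all features (using the planted DE list);
the hub attains the minimum DH on the variance-capped (top 500) network;
the adjusted Rand index between planted and detected module labels,
computed over features planted in modules (grey means "unassigned", so
background features are excluded from the comparison; the mRNA layer is
the primary metric and the miRNA layer a diagnostic); the detected module
holding the majority of the driver module's members attains the largest
|module-trait r|; and a retained cross-layer pair matches the planted
pair by member majority. Module detection for recovery runs on all 30
samples — the planted modules are not condition-specific, while the
pipeline's per-group split probes condition-specific wiring.

The default problem sizes (2,000 + 150 features, 30 samples, 20 seeds for
recovery, 200 replicates for the null false-discovery check, 100 random
instances for the PCIT oracle) keep the full test and acceptance runs in
the minutes range on a single core while leaving all recovery margins
comfortably away from their thresholds.

# Numerical choices and degenerate inputs

Correlations are clamped to [-1, 1] before p-value transforms; the PCIT
skip rules above guard the partial-correlation denominators; IRLS clamps
the linear predictor to +/-30 and caps iterations at 50 (non-convergence
is flagged, not silently accepted); eigengene signs follow the
positive-mean-membership rule; all rankings break ties lexicographically
by feature id so every output is deterministic; and the pipeline writes
provenance headers (version, seed, config hash) so reruns are verifiably
byte-identical.

# Known limitations

The DE stage trades the efficiency of shrinkage estimators for
transparency; at n = 15 + 15 its power on features with strong shared
biological variation (module members) is materially lower than on
independent features. The static module cut is less adaptive than dynamic
tree cutting on real, unevenly structured dendrograms. PCIT at
transcriptome scale requires the variance cap or external parallelism.
Seed matching ignores site context. Module-trait selection at p < 0.1 is
intentionally anti-conservative. All thresholds are plain function
arguments, so each of these trade-offs can be revisited per dataset.
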