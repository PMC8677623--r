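---
title: "Discovering tumor-microenvironment patterns: models, parameters and design choices"
author: "tmepatterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering tumor-microenvironment patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
what each stage assumes, which tunable parameters matter and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and where the design was genuinely open.

## The pipeline in one paragraph

Multi-patient single-cell RNA-seq of tumor and matched normal lung tissue
is quality-filtered, log-normalized and reduced to highly variable genes;
cells are embedded by PCA, connected in a shared-nearest-neighbor (SNN)
graph and clustered by Louvain modularity optimization; clusters are
annotated against reference marker signatures and epithelial clusters
dominated by tumor-tissue cells are called tumor. Two products are then
derived. First, per-patient cluster proportions within the myeloid,
lymphoid, endothelial and fibroblastic compartments are z-scored and
decomposed by PCA: the first component separates two microenvironmental
archetypes (N³MC and CP²E), and cluster co-occurrence is summarized by a
Spearman correlation network. Second, PC1 of tumor-cell expression gives a
differentiation axis whose extreme correlates — 30 genes per pole — form
alveolar/club-like and undifferentiated tumor-cell signatures. Both kinds
of signature are transferred to bulk cohorts by single-sample GSEA, and
median dichotomization of the CP²E-minus-N³MC score is tested for survival
separation by log-rank and Cox regression. Ligand–receptor signaling
between clusters is assessed with a label-permutation test.

## Quality control

Cells are kept when genes detected lie in [500, 10000], UMIs in
[1000, 100000], mitochondrial read fraction is **strictly** below 0.30 and
hemoglobin fraction strictly below 0.05. The count bounds are inclusive
and the fraction bounds strict, following the convention that a printed
range is inclusive while an inequality is strict. Mitochondrial genes
are recognized by the `MT-` symbol prefix and hemoglobin genes by the
explicit list HBA1, HBA2, HBB, HBD — common practice rather than a
published definition. The filter is idempotent, and its report counts a
cell under every rule it violates, so rule counts can exceed the number of
removed cells.

## Normalization and variable genes

Counts are normalized as `log(1 + count / cell_total * 1e4)`. The original
study used a regularized negative-binomial variance stabilization; we use
log-normalization plus standardized-variance HVG selection instead, a
deliberate substitution isolated behind the preprocessing interface:
everything downstream (clustering, scoring, proportions) consumes only a
normalized matrix and an HVG set, so an alternative normalizer can be
slotted in without touching other stages. HVGs are ranked by the variance
of z-scores standardized against a loess mean–variance trend (span 0.3,
degree 2, fitted on log10 scale), with z-values clipped at `sqrt(n_cells)`
— the standard variance-stabilizing selection. Constant genes get
standardized variance zero and can never outrank a variable gene.

## Clustering

PCA operates on per-gene z-scores clipped at ±10 (clipping protects
against single-cell outliers dominating a component). Components are
ordered by explained variance and each component's sign is fixed so its
largest-magnitude loading is positive — an arbitrary but reproducible
convention that makes embeddings comparable across runs. The SNN graph
uses k = 20 Euclidean nearest neighbors (self included), Jaccard edge
weights, and prunes edges below 1/15; Louvain runs at resolution 0.8.
These are the defaults of the standard single-cell toolkits, chosen
because the study names the toolkit but not the parameters; all are
exposed as arguments. Cluster annotation assigns each cluster the
reference signature with the highest mean module score (ties broken by
margin, then lexicographically) and inherits its compartment; a cluster
with no positive score is labeled `unassigned` rather than forced.
Epithelial clusters with tumor-tissue fraction ≥ 0.9 are called tumor —
the threshold operationalizes "overrepresented in tumor tissue" and is
consistent with the > 90% purity such clusters showed; it is exposed as
`min_tumor_frac`.

## Scores

The module score bins genes into 24 equal-size bins of mean expression and
samples 100 control genes per signature gene from the gene's bin
(excluding signature genes, with replacement only when the bin is
smaller). The sampling seed is an explicit parameter — the upstream
implementation is session-dependent, which makes scores irreproducible;
here identical seeds give identical scores. Pathway activity multiplies
per-gene z-scores (sd floored at 1e-8 to tolerate near-constant genes)
with a gene × pathway weight matrix and re-z-scores per pathway; the
package ships a small synthetic weight table for testing
(`pathway_weights_synthetic.tsv`) and accepts any published footprint
weight matrix as a drop-in TSV, since such weights are external model data
rather than something this pipeline derives.

## Markers

Marker detection keeps positive markers only, with natural-log fold
change ≥ 0.25 computed as `log(mean(expm1(in)) + 1) −
log(mean(expm1(out)) + 1)` (the convention of the major toolkit, tested
against a hand-computed fixture), expressing fraction (normalized value
> 0) inside ≥ 0.25, and inside-minus-outside fraction difference ≥ 0.25.
P-values are two-sided Wilcoxon rank-sum: exact enumeration over all
group assignments when both groups have ≤ 10 cells, otherwise the normal
approximation with tie correction and no continuity correction.
Bonferroni adjustment over the genes tested per cluster is reported but
not used as a filter, because the stated marker criteria contain no p
cutoff. Rows order by p, then decreasing fold change, then gene name — the
final tie-break is our convention for determinism.

## The differentiation axis

PC1 of z-scored HVG expression of tumor cells is oriented so it correlates
positively with the mean module score of normal alveolar/club reference
programs; if that correlation is numerically zero the function demands an
explicit orientation rather than guessing. Per-gene Pearson correlations
with the oriented PC1 are computed over genes detected in ≥ 1% of tumor
cells (configurable; correlation of a constant gene is defined as 0 and
constant genes never enter a signature), and the top 30 positive and top
30 negative correlates form the two signatures. Thirty per pole is the
defining size of these signatures; fewer are returned only when the
non-constant gene universe is smaller than 60, with a warning.

## Composition patterns

Proportions are computed per patient within each compartment over
tumor-tissue cells only, so compartment rows sum to one per patient.
Clusters occurring in fewer than 3 patients are excluded, and remaining
proportions are deliberately **not** renormalized — they keep their
original compartment denominators. "Normalized proportion" is interpreted
as the per-cluster z-score across patients (heat-map rows centered per
cluster); all compartments' columns are concatenated into a single matrix
for one PCA. Group assignment is by PC1 sign with the CP²E anchor-cluster
loadings fixed positive — a two-group split ordered along PC1 rather than
a clustering, because the phenomenon being modeled is exactly two
archetypes at opposite ends of one axis. The correlation network uses
Spearman rho with average ranks, exact permutation p-values for ≤ 9
patients (all n! rank permutations) and the t approximation above that,
retaining only rho > 0.7 with p < 0.05 — note the rule keeps positive
co-occurrence only. Pattern signatures are unions of member-cluster
markers with genes shared between the two patterns removed from both, so
the signatures are disjoint by construction. The 20-gene compact signature
takes 10 genes per pattern round-robin over member clusters in marker-rank
order; the original derivation of the simplified signature is not
documented anywhere, so this deterministic rule is our stated convention.

## Bulk translation and survival

ssGSEA follows the classical running-sum definition: per sample, genes are
ranked by expression (average ranks on ties), in-set genes contribute
weights `|rank|^0.25`, and the score sums the difference between the
weighted in-set ECDF and the uniform out-of-set ECDF along the ranked
list; normalization divides the whole score matrix by its global range.
The score being rank-based, any monotone transform of a sample's
expression leaves its scores unchanged. Patients are combined by the
**difference** ES(CP²E) − ES(N³MC) by default: the legend language
suggests a ratio, but normalized enrichment scores can be zero or
negative, making ratios undefined or unstable, while the difference is
rank-equivalent for positive scores and defined everywhere (the ratio
remains available behind `mode = "ratio"`). Median dichotomization sends
ties to the low group (a score equal to the median counts as low), and is applied to normalized
scores (normalization being the default of standard ssGSEA
implementations). Survival
uses Kaplan–Meier product-limit curves, the two-group log-rank statistic,
and univariate Cox regression with Breslow tie handling; perfect
separation (monotone partial likelihood) is reported as an error since
penalized fitting is out of scope, as is multivariate Cox (the covariates
used in the original multivariate analysis are not specified).

## Ligand–receptor testing

A pair is tested for a sender/receiver cluster pair only when ligand and
receptor are each expressed in ≥ 10% of the respective cluster's cells;
heteromeric complexes require every member and aggregate by the member
minimum. The statistic is the mean of the two cluster means, and the null
shuffles cluster labels over all cells, with one-sided p = fraction of
permuted statistics ≥ observed — the convention of the CellPhoneDB family
of tools. An exact mode enumerates all distinct two-cluster label
assignments, used by the tests to pin the sampling approximation to an
exhaustive oracle. The shipped 40-pair table covers the Ephrin, FGF, WNT,
TGFb, BMP and JAK/STAT families with known human ligand–receptor
pairings; it is a small curated stand-in for a full interaction database,
which can be supplied as a TSV with the same three columns.

## The synthetic generator

The generator is first-class, tested code that defines the study
conditions for validation. Eleven cell-type programs mirror the annotated
cluster repertoire (tumor and alveolar epithelium, two myofibroblast
states, two monocyte-derived macrophage states, two dendritic-cell types,
NK, conventional T, exhausted CD8 T, endothelium), each with 20 disjoint
marker genes boosted `exp(2)`-fold in its own cells. Counts are negative
binomial with dispersion 0.3 — typical overdispersion for droplet UMI
data — and lognormal library sizes (meanlog 9, sdlog 0.3, median ≈ 8100
UMIs). Patient composition is Dirichlet-multinomial: archetype anchors
carry a two-fold concentration shift between N³MC and CP²E patients, and
the overall concentration scale (base 24) is set so that within-archetype
compositional variability stays below that shift — patients adhere to
their archetype, as the two cleanly separated patient groups in real
cohorts do. Tumor cells carry a differentiation latent
`u ~ N(center, 0.15)` truncated to [0, 1] (center 0.75 for N³MC, 0.25 for
CP²E); a planted 30-gene alveolar-like program scales as `exp(2u)`, a
30-gene undifferentiated program as `exp(2(1−u))`, and the normal
alveolar program's markers scale at half strength with `u` — real
differentiated tumor cells partially re-express normal alveolar/club
genes, and this coupling is what gives the axis-orientation anchor its
signal. QC-artifact cells each violate exactly one rule (library
concentrated into 100 genes; mitochondrial counts equal to the rest of
the library, fraction 0.5; hemoglobin at ≈ 7.4%), making filter
attribution exactly testable. Bulk samples are pseudobulk mixtures of the
program mean-expression vectors under archetype proportions with
Gaussian log-scale noise; survival is exponential with rate
`λ0 exp(β·1[CP²E])` and independent exponential censoring tuned to the
target censoring fraction.

What the generator does **not** emulate: doublets, ambient RNA, batch
effects, realistic gene–gene covariance beyond the program structure, and
cell types absent from the program list. Passing tests therefore show the
pipeline recovers structure of this planted form at realistic noise
levels — they do not certify performance on artifacts the generator omits.

## Problem sizes and numerical choices

The test suite validates statistics against independent oracles at small
sizes where enumeration is exact (6 vs 6 Wilcoxon, 7-patient Spearman,
C(12,6) label assignments for ligand–receptor, a 6-subject hand-computed
log-rank) and recovery at moderate sizes chosen as the smallest where the
planted structure is comfortably identifiable: cohorts of 10 patients ×
300–500 cells for pattern recovery, ≈ 1000 tumor cells for the axis, and
bulk cohorts of 200–300 samples with 60–100 replicates for power and
calibration. Numerical guards: standard deviations floored at 1e-8 before
z-scoring, PC sign conventions as above, an explicit error when the axis
orientation anchor is within 1e-6 of zero, and Wald confidence intervals
`exp(β ± 1.96 se)`.

## Known limitations

Cluster labels, not cells, carry the annotation, so a mixed cluster is
labeled by its dominant program; sub-clustering is supported only by
re-running the same operations on a compartment subset. The pattern PCA
presumes exactly two archetypes; cohorts with more structure would need
the k-medoids alternative or more components. The ssGSEA normalization
divides by the global score range, so adding signatures or samples changes
normalized values (not their ranks within a signature). Copy-number
inference, doublet detection, UMAP-based analysis, and TCGA retrieval are
intentionally out of scope.
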