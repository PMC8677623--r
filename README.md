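# tmepatterns

Lung adenocarcinomas differ not only in their malignant epithelial cells
but in the composition of their tumor microenvironment (TME) — the
fibroblasts, macrophages, dendritic cells, T/NK cells and endothelium that
surround them. `tmepatterns` implements a complete analysis pipeline that,
given multi-patient single-cell RNA-seq of tumor and matched normal
tissue, (i) discovers recurring TME composition patterns across patients,
(ii) derives a tumor-cell differentiation axis with gene signatures at its
two poles, and (iii) translates both kinds of signature to bulk expression
cohorts, where they stratify patients into prognostic groups.

The package targets computational biologists who want the whole chain —
from raw 10x-style count matrices to survival curves — as small, tested,
composable functions, together with a synthetic-data generator that plants
known ground truth at every level so each stage can be validated.

## The two patterns

Across patients, cluster proportions within the myeloid, lymphoid,
endothelial and fibroblastic compartments co-vary in two recurring
configurations:

* **N³MC** — normal-like myofibroblasts, non-inflammatory monocyte-derived
  macrophages, NK cells, myeloid dendritic cells, conventional T cells;
  associated with alveolar/club-like (differentiated) tumor cells.
* **CP²E** — cancer-associated myofibroblasts, proinflammatory
  monocyte-derived macrophages, plasmacytoid dendritic cells, exhausted
  CD8⁺ T cells; associated with undifferentiated tumor cells and worse
  outcome.

Patients are placed on this axis by PCA of the z-scored patient × cluster
proportion matrix (clusters present in < 3 patients excluded), with the
PC1 sign anchored so CP²E-typical clusters load positively.

## Methods at the core

* **QC filtering** — cells kept with 500–10,000 genes detected,
  1,000–100,000 UMIs (inclusive), mitochondrial fraction < 30% and
  hemoglobin fraction < 5% (strict).
* **Module score** — for signature *S*, genes are placed in 24 equal-size
  bins of average expression; each signature gene draws 100 control genes
  from its bin, and
  `score(c) = mean_{g∈S} x_gc − mean_{g∈ctrl} x_gc`.
* **ssGSEA** — per sample, genes are ranked by expression; with weights
  `|r_g|^α` (α = 0.25) the enrichment score is the sum over the ranked
  list of the weighted in-set ECDF minus the uniform out-of-set ECDF,
  optionally normalized by the global score range.
* **Marker detection** — per-cluster Wilcoxon rank-sum on normalized
  expression with the filters log-FC ≥ 0.25 (natural log, on
  `mean(expm1(·))+1`), in-cluster expressing fraction ≥ 0.25 and
  fraction difference ≥ 0.25; exact enumeration when both groups ≤ 10.
* **Differentiation axis** — PC1 of z-scored HVG expression of tumor
  cells, oriented by correlation with normal alveolar/club reference
  scores; the 30 genes most positively / negatively correlated with PC1
  form the alveolar/club-like and undifferentiated signatures.
* **Survival** — Kaplan–Meier curves, the log-rank statistic
  `(O−E)²/V` with hypergeometric variance, and univariate Cox
  proportional-hazards regression (Breslow ties) reporting
  `HR = exp(β)` with Wald 95% CI.
* **Ligand–receptor testing** — CellPhoneDB-style: pair score = mean of
  ligand mean in sender and receptor mean in receiver (complexes by member
  minimum), p from permutation of cluster labels.

## Worked example

```r
library(tmepatterns)

sim <- simulate_sc_cohort(n_patients = 6, cells_per_patient = 300,
                          qc_artifact_frac = 0.05, seed = 42)
qc <- qc_filter(sim$counts, sim$meta)
#> <qc_result> 2160 cells retained, 90 removed
nm  <- normalize_log(qc$counts)
hvg <- select_hvg(nm, 500)
ca  <- cluster_graph(build_snn(pca_embed(nm, hvg, 15), k = 20),
                     resolution = 0.8, seed = 1)
ca  <- annotate_clusters(ca, nm, program_signatures(default_cell_programs()))
ca  <- call_tumor_clusters(ca, qc$meta)
#> 12 clusters; e.g. cluster 2 = tumor_cell (epithelial, tumor),
#> cluster 7 = alveolar_epithelial (epithelial, normal)

ct <- filter_rare_clusters(compute_proportions(ca, qc$meta))
pa <- pattern_pca(ct)
round(pa$pattern_pc1, 2)
#>   P01   P02   P03   P04   P05   P06
#> -2.66  2.31 -2.78  2.28 -1.72  2.56
```

The six patients split cleanly: negative PC1 (P01, P03, P05) are N³MC,
positive (P02, P04, P06) are CP²E — exactly the archetypes the generator
planted. Translating the pattern signatures to a simulated bulk cohort
with a two-fold CP²E hazard:

```r
sb   <- simulate_bulk_cohort(n_samples = 300, survival_beta = log(2), seed = 42)
sigs <- assemble_pattern_signatures(program_signatures(default_cell_programs()))
es   <- ssgsea(sb$cohort, sigs)
grp  <- stratify_median(pattern_score(es, "CP2E", "N3MC"))
km_logrank(sb$cohort, grp)
#> log-rank chi2 = 15.0771, p = 0.0001032
cox_fit(sb$cohort, grp)
#> Cox HR = 1.718 (95% CI 1.303-2.264), p = 0.0001234
```

Samples whose CP²E-minus-N³MC enrichment score lies above the cohort
median experience events 1.7 times faster — the stratification recovers
the planted survival structure from expression alone.

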