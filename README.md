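# isgtkit

Type I interferon (IFN-I) signalling leaves a transcriptional fingerprint on
T cells: a minority subset upregulates interferon-stimulated genes (ISGs)
such as *ISG15*, *ISG20*, *IFIT1* and *IRF7*. These **ISG-T cells** expand in
the blood and inflamed kidneys of patients with autoimmune kidney disease
(ANCA-associated and lupus glomerulonephritis), and in tissue they sit close
to plasmacytoid dendritic cells (pDCs), the main IFN-I producers. `isgtkit`
packages the quantitative workflow needed to find and characterise these
cells in single-cell and imaging-based spatial transcriptomics data, for
computational biologists working with cell-by-gene count matrices and
per-cell coordinates.

## What it computes

**Module score.** For a gene program *G* and cell *c*, on log-normalized
expression *x*:

    score(c) = mean_{g in G} x_cg  -  mean_{g' in ctrl(G)} x_cg'

where the control pool `ctrl(G)` draws, for every program gene, `n_ctrl`
random genes from that gene's equal-frequency expression bin (`n_bins` bins
over mean expression, defaults 24 bins / 100 controls). Matching controls to
the program's expression level centres the null at zero. ISG-T cells are
called by thresholding the score (default: mean + 3 SD of the reference
cells' scores) and summarised as per-sample frequencies among T cells.

**Nearest-focal proximity.** Within each biopsy sample, for every non-focal
cell *i* the statistic is the minimum Euclidean distance (in µm) to the
focal type *F*:

    d_i = min_{j in F} || p_i - p_j ||

Per-type medians of `d` (pooled across cells, or median of per-sample
medians) feed a star network with the focal type at the hub and a
closest-neighbour ranking within lymphocyte / non-lymphocyte lineages;
condition contrasts use one-way ANOVA with Tukey HSD (or rank-sum / Welch
t tests).

Supporting stages: QC filtering (min genes per cell, total-count window,
min cells per gene), two log-normalization dialects (target 10,000 + log2
for sequencing-based spatial data; target 1,000 + natural log for
imaging-based panels), reference-based cell typing by cross-validated
multinomial ridge logistic regression, and negative-binomial expression /
clustered-tissue simulators with ground truth.

## Worked example

```r
library(isgtkit)

# a tissue cohort: ISG-T cells clustered around pDCs (sigma = 30 um) in
# "disease", placed uniformly in "control"; 5 biopsies per condition
cohort <- simulate_cohort(
  list(disease = tissue_sim_spec(attraction_sigma_um = 30),
       control = tissue_sim_spec(attraction_sigma_um = Inf)),
  n_samples_per_condition = 5, base_seed = 1001)

records <- nearest_focal_distances(cohort$map, cohort$cells, "ISG-T")
medians <- median_distance_by_type(records, "pooled_cells", by_condition = TRUE)
medians[medians$cell_type == "pDC", c("condition", "median_um", "n_cells")]
#>   condition median_um n_cells
#> 5   control  99.90258     250
#> 12  disease  25.43598     250

rank_neighbors(median_distance_by_type(
  records[records$condition == "disease", ], "pooled_cells"), "ISG-T")
#> proximity_network: ISG-T at the hub, 7 neighbour types
#>   lymphocyte: closest = Tn (median 128.81 um; 2 types)
#>   non_lymphocyte: closest = pDC (median 25.44 um; 5 types)

compare_conditions(records, cell_type = "pDC", test = "anova_tukey")
#> condition_comparison (anova_tukey, cell type pDC)
#>  condition   n   median      mean
#>    control 250 99.90258 105.66346
#>    disease 250 25.43598  42.43402
#>   statistic = 159.7, p = 5.95e-32
```

The disease cohort's pooled median pDC → ISG-T distance (~25 µm) is a
quarter of the control cohort's (~100 µm), and pDC ranks first among
non-lymphocyte neighbours — the spatial signature of local T-cell
activation next to IFN-I-producing pDCs. On the expression side,
`simulate_expression()` + `score_program()` + `call_isgt()` recover a
5% ISG-T subset planted at 4-fold ISG induction with sensitivity and
specificity above 0.9 (see `vignettes/isgt-workflow.Rmd`).

## Reproducible acceptance run

`scripts/acceptance.R` re-runs the whole workflow from scratch — simulating
an expression matrix with a planted ISG program, QC, normalization, scoring
and ISG-T calling, then a two-condition tissue cohort with nearest-ISG-T
distances, median network and ANOVA/Tukey comparison — and writes its
results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`.
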