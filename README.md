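# metaniche

Comparative single-cell analysis of metastatic bone-marrow niches.

`metaniche` is an R package for cohort-scale comparative scRNA-seq analysis
of tumor metastasis, built around the workflow used to contrast bone-marrow
samples from metastatic and nonmetastatic neuroblastoma patients. It covers
the full path from raw counts to survival read-out:

- **QC**: remove cells with fewer than 600 total UMIs or a doublet score
  above 0.4.
- **Composition**: per-sample cell-type proportions compared between
  conditions with two-sided Wilcoxon rank-sum tests (exact for small
  cohorts).
- **Signature scoring**: per-cell or per-sample unweighted mean of
  normalized expression over a gene set.
- **Marker / differential expression**: Wilcoxon rank-sum with signed
  Z = sign(Δ mean rank) · Φ⁻¹(1 − p/2) and the Z > 3 marker rule, plus
  per-sample "mini-bulk" (pseudobulk) negative-binomial Wald tests with
  median-of-ratios size factors and trend-moderated dispersions (samples
  need ≥ 10 cells of the type to enter).
- **CNV inference**: reference-centered, clipped, moving-average expression
  profiles along chromosomes (101-gene window), with segment calling
  against the reference distribution.
- **Metastatic signature**: genes with Z > 10 both against primary tumor
  cells and against non-malignant cells; bulk cohorts are stratified into
  top/bottom 25% by signature score and compared with Kaplan–Meier curves
  and the two-group log-rank test.
- **Ligand–receptor interactions**: CellPhoneDB-style product-of-means
  scores over (sender, receiver) cell-type pairs, screened at 10%
  expression fraction, with an empirical p-value from 1,000 global
  shuffles of cell identities (add-one convention).

A synthetic cohort generator (`generate_sc_cohort()`,
`generate_bulk_cohort()`, `generate_lr_database()`) plants known
composition shifts, tumor-exclusive genes, copy-number segments, doublets
and survival hazards, so every stage is testable end to end with ground
truth and no external downloads.

## Worked example

Simulate the default cohort (8 metastatic, 7 nonmetastatic bone-marrow
samples, 3 primary-tumor samples; 2,000 genes), filter it, and derive the
metastatic signature:

```r
library(metaniche)

sim <- generate_sc_cohort(sim_config(seed = 1))
qc  <- filter_cells(sim$counts, sim$cells)        # 3415 -> 3243 cells
norm <- normalize_counts(qc$counts)

composition_test(qc$cells, "metastatic", "nonmetastatic") |> tidy()
#>   cell_type   n_a   n_b median_a median_b    p_val
#> 1 B_cell        8     7   0.113     0.176 0.00373
#> 2 NK_cell       8     7   0.0608    0.111 0.0140
#> 3 T_cell        8     7   0.123     0.344 0.000622
#> 4 myeloid       8     7   0.453     0.345 0.0289
#> 5 tumor         8     7   0.234     0     0.000795

der <- derive_signature(norm, qc$cells, z_cutoff = 10)
#> <mn_signature_derivation> Z > 10 in both comparisons: 30 genes
```

The composition table shows the planted design: tumor cells appear only in
metastatic samples (median proportion 0.23 vs 0), the myeloid compartment
expands and T cells contract in the metastatic arm. The derived signature
recovers all 30 planted tumor-exclusive genes with no false members.

Evaluate the signature on a bulk cohort with a planted hazard:

```r
bulk   <- generate_bulk_cohort(200, der$signature, hazard_ratio = 3, seed = 1)
scores <- score_signature(bulk$expr, der$signature)
strat  <- stratify_by_score(scores, quantile = 0.25)   # top/bottom 25%
surv <- dplyr::inner_join(bulk$survival, strat, by = c(patient_id = "id")) |>
  dplyr::filter(stratum != "excluded")
logrank_test(surv, "high", "low")
#> <mn_logrank> high vs low: chi-square = 76.98 on 1 df, p = 1.726e-18
autoplot(km_estimate(surv))
```

High-signature patients have sharply worse survival, as designed. Result
objects have `tidy()` / `glance()` methods and `plot_*()` / `autoplot()`
views (`plot_composition()`, `plot_cnv_profile()`, `plot_lr_dotplot()`).
`run_pipeline(pipeline_config())` executes every stage in dependency order
and writes tab-delimited tables plus a manifest.

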