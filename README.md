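# tnbcmodules

Molecular phenotyping of triple-negative breast cancer (TNBC) expression
cohorts profiled on degraded FFPE material, with AQUA-style microvessel-area
quantification of tissue-microarray images.

## The problem

TNBC cohorts assembled from archival formalin-fixed, paraffin-embedded
(FFPE) blocks carry heavy RNA degradation. Arrays tolerant of such material
(WG-DASL style) return, for every probe and sample, an intensity *and* a
detection p-value, and the samples are processed on slides in batches —
so the analysis has to contend with widespread dropout, slide-level batch
artifacts, and confounding between patient groups and tumor stage.
`tnbcmodules` implements a complete, tested pipeline for this setting:

- **Detection-based QC** — keep the best primary-tumor sample per patient;
  drop samples with < 30% detectable probes and probes detectable in < 10%
  of samples; remove probes whose undetectable calls cluster as a
  consecutive run within one slide, using an exact longest-run tail
  probability: for a probe with overall detection rate *p*, the chance that
  *n* calls on a slide contain an undetectable run of length ≥ *k* is
  computed by dynamic programming and Bonferroni-adjusted over slides
  (removal at p < 1e-4); log2 transform, per-sample outlier masking
  (> 3 SD from the sample mean), and quantile normalization with
  rank-based imputation of masked cells.
- **Module discovery** — PCA of the normalized matrix ("projection
  scores" per probe), extraction of the 250 extreme-loading probes per
  component, one-sided Fisher/hypergeometric gene-set enrichment with
  BH-FDR, and GO enrichment with the *elim* decorrelation procedure
  (elimination threshold p < 0.01).
- **Signature activation scoring** — a sample's activation of a published
  signature is the Pearson correlation between the signature's gene-weight
  vector **w** and the sample's expression over those genes,
  *r*ᵢ = cor(**w**, **x**ᵢ). Group differences are tested by two-tailed
  Welch t-tests, stage confounding is removed by permuting group labels
  within tumor-stage strata (1000 resamples), and p-values are BH-FDR
  adjusted across signatures. A LAR-high (luminal androgen receptor)
  subgroup is called by k = 2 k-means on AR expression and LAR activation.
- **Angiogenesis** — a combined VEGF profile score per sample (mean of
  per-gene expression ranks), per-gene Welch tests with Bonferroni control,
  and microvessel area (MVA) from three-channel histospot images:
  cytokeratin → tumor mask (Otsu + closing, spots with < 5% tumor content
  excluded), DAPI → nuclear/non-nuclear partition, CD31 → vessel mask;
  MVA% = 100 · vessel px / tumor px, dichotomized at 0.6%.
- **Synthetic data** — generators for expression cohorts (planted group
  effects, stage confounding, slide-run artifacts, LAR-high subsets),
  negative-binomial count matrices, and histospot images with exact
  rendered pixel truth, so every stage of the pipeline is testable without
  downloads.

## Worked example

```r
library(tnbcmodules)

sigs <- synthetic_signatures(sizes = c(basal = 100, lar = 80, msc = 80),
                             n_genes = 2000, seed = 10)
cohort <- simulate_cohort(n_samples = 90, n_probes = 2000, signatures = sigs,
                          effect_sizes = c(basal = 1),  # +1 SD in AA samples
                          n_batch_probes = 5, seed = 42)

pp  <- preprocess_pipeline(cohort$matrix, cohort$annotation)
act <- score_signatures(pp$matrix, sigs)
test_activation(act, cohort$annotation, n_resamples = 999, seed = 7)
#>   signature mean_AA mean_EA n_AA n_EA     t    p_raw stage_adjusted_p   fdr
#> 1     basal  0.5003  0.0834   41   49 55.68 7.06e-69            0.001 0.003
#> 2       lar -0.1310 -0.1161   41   49 -1.42 1.59e-01            0.152 0.152
#> 3       msc -0.0654 -0.0491   41   49 -1.67 9.94e-02            0.095 0.143
```

The planted basal-signature effect is recovered (mean activation 0.50 in AA
vs 0.08 in EA; the stage-stratified permutation p reaches its floor of
1/1000), while the unplanted signatures stay null. The QC report shows the
five planted slide-run probes removed by the batch filter
(2000 → 1995 probes). Module discovery ties the planted signature to a
principal component and recovers its gene set:

```r
pca  <- run_pca(pp$matrix)
spearman_pc_signature(pca$scores[, 1], act[, "basal"])
#> [1] -0.884
sel <- probes_to_genes(top_probes(pca, 1, 250, "top"), pp$matrix)
coll <- structure(lapply(sigs, `[[`, "genes"), class = "gene_set_collection")
universe <- probes_to_genes(rownames(pp$matrix$values), pp$matrix)
fisher_enrichment(sel, coll, universe)[, c("set", "set_size", "overlap", "p", "fdr")]
#>     set set_size overlap        p      fdr
#> 1 basal      100      43 4.31e-16 1.29e-15
#> 3   msc       80       7 8.57e-01 9.29e-01
#> 2   lar       80       6 9.29e-01 9.29e-01
```

Image quantification on a synthetic histospot:

```r
sim <- simulate_histospot(vessel_fraction = 0.02, seed = 25)
quantify_spot(sim$spot)     # MVA ~2.0%, called high (> 0.6%)
```

Small synthetic example inputs (expression TSV with detection companion,
annotation CSV, weighted-signature TSV, GMT, OBO-lite GO DAG) ship under
`inst/extdata/`; they are stand-ins generated by the package's own
simulators, not published gene lists.

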