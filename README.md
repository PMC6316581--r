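# ptcnmf

Metagene deconvolution and immune classification of papillary thyroid
carcinoma (PTC) expression profiles.

Bulk tumor transcriptomes are cellular mixtures. `ptcnmf` factorizes a
non-negative genes × samples expression matrix *V* (log2-transformed
RSEM/FPKM-style values) into metagene signatures *W* and per-sample
activities *H*,

    V ≈ W H,   W ≥ 0, H ≥ 0,

by multiplicative updates minimizing the generalized Kullback–Leibler
divergence D(V‖WH). In PTC three signatures carry the dominant structure — a
RAS-like program, a BRAF-like program, and an immune program — and the
immune signature splits each driver side into immunoreactive (IR) and
immunodeficient (ID) subgroups, giving four clusters: NMF1/RAS-IR,
NMF2/RAS-ID, NMF3/BRAF-IR, NMF4/BRAF-ID. NMF3/BRAF-IR marks immune-hot
BRAF-like tumors with elevated recurrence risk.

The package is for computational biologists who want this pipeline as
tested, reusable components rather than a one-off script:

* **NMF core** — seeded KL-divergence factorization (C++ inner loop),
  consensus matrices over restarts, cophenetic stability, rank selection
  (`nmf_factorize`, `consensus_matrix`, `rank_survey`, `select_rank`).
* **Classification** — Ward clustering of activities, signature annotation
  from driver labels, four-cluster labeling, pseudoinverse metagene
  projection onto external cohorts (`cluster_samples`,
  `annotate_signatures`, `label_clusters`, `project_metagenes`,
  `classify_external`).
* **Immune profiling** — cytolytic (CYT) score, mean-z signature scores,
  NNLS reference-based cell fractions, pre-ranked enrichment scores,
  feature–signature correlations (`cyt_score`, `signature_score`,
  `nnls_cell_fractions`, `preranked_enrichment`,
  `feature_signature_correlation`, `cluster_feature_summary`).
* **Recurrence statistics** — 2×2 odds ratios with Wald intervals, logistic
  models, chi-square/Fisher tests, Kaplan–Meier, log-rank and Cox models,
  and assembled univariate/multivariate recurrence tables
  (`odds_ratio_wald`, `logistic_fit`, `km_estimate`, `logrank_test`,
  `cox_fit`, `build_table2`, `build_table3`).
* **Synthetic cohorts** — a seeded generator planting rank-3 structure, four
  clusters, immune marker genes, cluster-linked recurrence, and external
  immune features at known correlations (`generate_cohort`,
  `synthetic_config`, `write_cohort`), so every stage can be tested against
  ground truth.
* **Pipeline** — `validate_config()` / `run_pipeline()` orchestrate
  preprocess → NMF → classify → immune → association with a reproducibility
  manifest; `inst/scripts/ptcnmf-pipeline.R` is a thin command-line wrapper.

## Worked example

```r
library(ptcnmf)

# simulate a cohort with known structure (2000 genes x 400 samples)
cohort <- generate_cohort(synthetic_config(seed = 1))
E <- log_transform(cohort$expression)

# factorize at rank 3 and name the signatures from driver labels
fit <- nmf_factorize(E, k = 3, seed = 1)
ann <- annotate_signatures(fit$activity, cohort$driver_label,
                           cyt_score(cohort$expression))
#> SignatureAnnotation: signature1=RAS, signature2=Immune, signature3=BRAF

# four clusters, named RAS-IR / RAS-ID / BRAF-IR / BRAF-ID
assignment <- label_clusters(cluster_samples(fit$activity), ann, fit$activity)
table(assignment$label)
#>  RAS-IR  RAS-ID BRAF-IR BRAF-ID
#>      52      76     127     145
mean(as.character(assignment$cluster) == as.character(cohort$true_cluster))
#> [1] 0.9975

# immune features vs estimated signature activities
round(feature_signature_correlation(fit$activity, cohort$features)[,
  c("leukocyte_fraction", "tcr_richness", "tumor_purity")], 2)
#>            leukocyte_fraction tcr_richness tumor_purity
#> signature1              -0.29        -0.24         0.24
#> signature2               0.82         0.72        -0.70
#> signature3               0.00        -0.03         0.03
```

The clusters recover the simulated truth almost perfectly, and only the
immune signature tracks the leukocyte/TCR/purity features — positively for
immune infiltration, negatively for tumor purity — at the correlations the
generator planted (0.8, 0.73, −0.71).

Recurrence association for the BRAF-IR cluster, from the published TCGA
event/total counts shipped with the package:

```r
counts <- subset(tcga_recurrence_counts(), variable == "nmf_cluster3")
orw <- odds_ratio_wald(two_by_two(20, 133, 19, 307))
#> NMF3 recurrence OR 2.43 (95% CI 1.26-4.70), p = 0.008
```

BRAF-IR tumors recur at 13.1% (20/153) versus 5.8% (19/326) for the other
clusters — roughly 2.4-fold odds.

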