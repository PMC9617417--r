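# nascore

Prognostic scoring of bulk tumour transcriptomes from neoantigen-coding,
RNA-modification-correlated lncRNAs.

Gliomas (and other tumours) express long non-coding RNAs whose small open
reading frames can produce MHC-class-I-presentable peptides — candidate
neoantigens. `nascore` implements a pipeline that turns such lncRNAs into a
per-sample **neoantigen activation score (NAS)**:

1. screen lncRNAs correlated with pseudouridine (Ψ), m5C and m1A
   RNA-modification regulators (|r| ≥ 0.4, p ≤ 0.001, `cor.test`);
2. keep MHC-I peptide-coding candidates with univariate Cox p < 0.05 and
   partition them by hazard ratio (risk, HR > 1, vs protective, HR < 1);
3. derive two sample clusters by resampling consensus k-means (euclidean,
   k scanned over 2..9, chosen by cluster-consensus), orienting cluster 2
   as the aggressive cluster;
4. call differentially expressed genes between clusters as the
   intersection of three engines (moderated-t, rank-sum, NB exact) at
   FDR < 0.05 and |log2FC| > 1, with a single-engine fallback at 0.4;
5. score each sample with the HR-signed, PCA-weighted sum

   `NAS = k·Σ_{HR>1} x_g·(PC1_g + PC2_g) − k·Σ_{HR<1} x_g·(PC1_g + PC2_g)`

   where `x` is FPKM-scale expression, `PC1 + PC2` is the gene's summed
   loading on the first two principal components, and `k = 1e-4`;
6. transfer the cluster model to validation cohorts with a radial-kernel
   SVM (75/25 split, 10-fold CV) and evaluate survival with Kaplan–Meier
   curves, the log-rank test and ROC AUC.

A synthetic cohort generator (Gaussian-copula correlation structure,
negative-binomial counts, exponential proportional-hazards survival with
independent censoring) plants every assumption the pipeline makes, so the
whole analysis is testable offline. The package also ships the published
five-gene simplified score
(`0.2286·COL5A2 + 0.1084·PVT1 + 0.0738·CHI3L2 + 0.0360·SERPINE1 + 0.0245·SOCS3`)
as `simplified_nas()`, plus `fit_simplified_signature()` to refit such a
sparse model by L1-penalized Cox regression.

## Worked example

```r
library(nascore)

config <- nas_config(seed = 1, k_range = 2:5, reps = 100)
report <- run_nas_pipeline(config, sim_params(seed = 1),
                           validation_cohort = TRUE)
report
#> NAS pipeline report
#>   config e46da572, seed 1
#>   signature genes: 12 | k chosen: 2 | DEGs: 112 (intersection)
#>   NAS range: [1.472, 5.5]
#>   log-rank p (NAS groups): 0.000501 | AUC: 0.597
#>   transfer holdout accuracy: 1.000

head(round(report$nas$nas$nas, 4))
#>   S001   S002   S003   S004   S005   S006
#> 1.7313 1.5873 1.7436 1.7526 1.8116 1.8882
```

Reading the report: all 12 planted MHC-I-coding lncRNAs enter the
signature; consensus clustering picks k = 2 and recovers the planted
clusters; the three-engine intersection finds 112 DEGs (the 100 planted
DEG-block genes plus the 12 signature lncRNAs, no background false
positives); the NAS separates its median-split high/low groups in overall
survival (log-rank p ≈ 5e-4), and the radial-SVM cluster model classifies
the held-out quarter of the cohort perfectly. Per-stage objects (edges,
Cox fits, consensus matrices, PCA weights, KM curves) hang off the report
for inspection. A thin command-line wrapper lives at
`inst/cli/nascore.R` (`simulate` and `run` subcommands).

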