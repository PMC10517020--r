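# omicsurv

Multimodal omics integration for survival prediction and subtype discovery.

## The problem

Predicting survival for non-small-cell lung cancer patients from any single
data modality — gene expression, miRNA, lncRNA, DNA methylation, or the
clinical record — leaves signal on the table: the hazard is driven by
biology that no single assay captures completely. `omicsurv` implements a
multimodal pipeline for right-censored survival built around three ideas:

1. **Supervised linear feature screening.** Each feature is scored with a
   univariate Cox proportional-hazards Wald test
   (h(t|x) = h₀(t)·exp(βx); Breslow ties; Newton solver with a
   monotone-likelihood guard). The top features per modality (500 for
   mRNA/methylation, 300 for miRNA/lncRNA) are retained — 1600 in total.
2. **Denoising-autoencoder integration.** The 1600 selected features are
   compressed to a 160-dimensional embedding by an autoencoder trained to
   reconstruct clean input from corrupted input (random zeroing or additive
   Gaussian noise; Adam, MSE, lr 0.001, early stopping). Early integration
   uses one autoencoder on the concatenated features; late integration
   compresses each modality separately (500→50, 300→30) and concatenates —
   160 columns either way. The 11 encoded clinical columns are appended
   afterward (171-wide survival input).
3. **Elastic-net Cox modeling and evaluation.** A regularized Cox model
   with penalty λ[α‖β‖₁ + (1−α)/2‖β‖₂²], α = 0.5, with λ chosen by
   cross-validated Harrell C-index; performance is the Harrell concordance
   index (0.5 = random, 1 = perfect) on held-out test patients across 5
   independent stratified 80/20 resplits.

A biomarker arm clusters patients with k-means on the elastic net's
surviving feature columns (K chosen by silhouette width over 2..10),
compares the groups with Kaplan–Meier curves and the log-rank test, and
runs negative-binomial Wald differential expression (BH-adjusted p < 0.05
and |fold change| > 1.5) plus M-value ANOVA differential methylation
(M = log2(β/(1−β)), probes averaged per gene, raw p < 0.05).

Real cohorts of this shape require a large controlled-access download, so
the package ships a synthetic multi-omics generator
(`sim_config()` / `generate_dataset()`) with known latent survival
structure, planted subtypes, tunable censoring and missingness, and a
ground-truth object — every pipeline stage is testable against planted
truth. See the methods vignette (`vignettes/omicsurv-methods.Rmd`) for the
generative model and all numerical conventions.

## Worked example

```r
library(omicsurv)

cfg <- sim_config(n_patients = 400,
                  features_per_modality = c(mrna = 500, mirna = 100,
                                            lncrna = 200, methylation = 600),
                  seed = 1)
gen <- generate_dataset(cfg)
print(gen$dataset)
#> multiomics_dataset: 400 patients (155 events, 245 censored)
#>   mrna            500 features (+ raw counts)
#>   mirna           100 features (+ raw counts)
#>   lncrna          200 features (+ raw counts)
#>   methylation     600 features
#>   clinical         13 columns
#>   cohorts: A=216, B=184

ec <- experiment_config(modalities = c("mrna", "lncrna", "clinical"),
                        n_runs = 5,
                        lfs_caps = c(mrna = 100, methylation = 100,
                                     lncrna = 60, mirna = 60),
                        ae = list(max_epochs = 30))
rep <- run_configuration(ec, gen$dataset, keep_states = TRUE)
print(rep)
#> run_report [mrna+lncrna+clinical | early | dr=lfs_ae]: mean C-index 0.876 +/- 0.008 over 5 run(s)
round(rep$c_indices, 3)
#> [1] 0.888 0.879 0.869 0.875 0.869
```

Each run is an independent stratified 80/20 resplit; the C-indices are
held-out test concordances, so ~0.88 means the model correctly orders 88%
of comparable test patient pairs. The subtype arm then uses one designated
run (median test C-index):

```r
st <- discover_subtypes(rep, gen$dataset)
print(st)
#> subtype_result: K = 2 (silhouette 0.469), log-rank chi2 = 246.26 (p = 1.7e-55),
#>   11 survival features, run 4

da <- differential_analysis(filter_patients_by_followup(gen$dataset), st$labels)
head(da$mrna[order(da$mrna$adj_p), c("id", "log2fc", "p", "adj_p", "significant")], 5)
#>          id    log2fc            p        adj_p significant
#>  mrna_00465 -4.211584 1.048400e-78 5.242001e-76        TRUE
#>  mrna_00192 -3.731624 3.795500e-71 9.488749e-69        TRUE
#>  mrna_00167 -3.851123 2.080690e-69 3.467816e-67        TRUE
#>  mrna_00267  3.437874 8.255872e-57 1.031984e-54        TRUE
#>  mrna_00185 -3.742882 4.882277e-54 4.882277e-52        TRUE
sum(da$mrna$significant)
#> [1] 46
```

The generator planted two survival subtypes; silhouette selects K = 2, the
groups differ sharply in survival (log-rank P = 1.7e-55), and the DE table
recovers the planted fold changes (log2FC here combines the direct planted
shift with subtype signal propagated through the latent loadings).

Other entry points: `sweep_modality_combinations()` (all 31 modality
subsets, ranked by mean C-index), `grid_search_autoencoders()` (the
21-configuration noise × activation grid), `compare_configurations()`
(Welch t-test between per-run C-index lists), and a CLI at
`inst/cli/omicsurv` with `simulate`, `run`, `sweep`, `compare` and
`subtype` subcommands driven by a JSON config.

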