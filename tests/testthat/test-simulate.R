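# Synthetic multi-omics generator: determinism, survival model
# self-consistency, censoring tuning, missingness, probe annotation and
# count marginals.

test_that("identical (config, seed) pairs give bit-identical datasets", {
  cfg <- sim_config(n_patients = 80,
                    features_per_modality = c(mrna = 50, mirna = 20,
                                              lncrna = 20, methylation = 60),
                    seed = 11)
  g1 <- generate_dataset(cfg)
  g2 <- generate_dataset(cfg)
  expect_identical(g1, g2)
  ann1 <- generate_probe_annotation(cfg, seed = 5)
  ann2 <- generate_probe_annotation(cfg, seed = 5)
  expect_identical(ann1, ann2)
  d1 <- inject_missingness(g1$dataset, 0.1, seed = 3)
  d2 <- inject_missingness(g2$dataset, 0.1, seed = 3)
  expect_identical(d1, d2)
  # a different seed changes the data
  g3 <- generate_dataset(sim_config(n_patients = 80,
                                    features_per_modality = cfg$features_per_modality,
                                    seed = 12))
  expect_false(identical(g1$dataset$survival, g3$dataset$survival))
})

test_that("survival signal endpoints: zero effect ~ 0.5, strong effect -> 1", {
  feats <- c(mrna = 30, mirna = 10, lncrna = 10, methylation = 30)
  cis_null <- vapply(1:5, function(s) {
    g <- generate_dataset(sim_config(n_patients = 300, features_per_modality = feats,
                                     effect_size = 0, subtype_latent_gap = 0,
                                     censoring_rate = 0, seed = s))
    # with no hazard signal anywhere the latent sum is pure noise
    risk <- rowSums(g$truth$latent_matrix[, 1:4])
    harrell_cindex(risk, g$dataset$survival$time_days, g$dataset$survival$event)$c_index
  }, numeric(1))
  expect_lt(abs(mean(cis_null) - 0.5), 0.05)

  g <- generate_dataset(sim_config(n_patients = 400, features_per_modality = feats,
                                   effect_size = 4, censoring_rate = 0, seed = 2))
  ci <- harrell_cindex(g$truth$true_linear_predictor,
                       g$dataset$survival$time_days, g$dataset$survival$event)
  expect_gt(ci$c_index, 0.95)
})

test_that("censoring tuning hits the target fraction within 0.05", {
  g <- generate_dataset(sim_config(n_patients = 2000,
                                   features_per_modality = c(mrna = 20, mirna = 5,
                                                             lncrna = 5, methylation = 20),
                                   censoring_rate = 0.6, seed = 9))
  realized <- mean(g$dataset$survival$event == 0)
  expect_lt(abs(realized - 0.6), 0.05)
})

test_that("injected missingness is at the requested rate and boundary rates work", {
  g <- small_gen()
  ds <- g$dataset
  # rate 0 leaves the dataset unchanged
  expect_identical(inject_missingness(ds, 0, seed = 1, elevated_frac = 0), ds)
  # rate 1 blanks everything
  d1 <- inject_missingness(ds, 1, seed = 1, elevated_frac = 0)
  expect_true(all(is.na(d1$modalities$mrna)))
  expect_true(all(d1$counts$mrna == 0))
  # rate 0.1 concentrates around 0.1 on >= 10,000 entries (on top of the
  # generator's default background missingness, measured relative to it)
  clean <- generate_dataset(sim_config(n_patients = 200,
                                       features_per_modality = c(mrna = 100, mirna = 10,
                                                                 lncrna = 10, methylation = 50),
                                       missing_rate = 0, elevated_missing_frac = 0,
                                       seed = 3))$dataset
  d2 <- inject_missingness(clean, 0.1, seed = 7, elevated_frac = 0)
  expect_lt(abs(mean(is.na(d2$modalities$mrna)) - 0.1), 0.01)
})

test_that("probe annotation structure supports the CpG filter", {
  cfg <- sim_config(features_per_modality = c(mrna = 10, mirna = 5, lncrna = 5,
                                              methylation = 100),
                    frac_probes_in_scope = 0.4, seed = 21)
  ann <- generate_probe_annotation(cfg, seed = 21)
  expect_equal(nrow(ann), 100)
  expect_false(anyDuplicated(ann$probe_id) > 0)
  in_scope <- ann$in_cpg_island & ann$upstream &
    !is.na(ann$distance_upstream_tss) & ann$distance_upstream_tss <= 1500
  expect_equal(sum(in_scope), 40)
  # downstream probes carry a sentinel, never a negative distance
  expect_true(all(ann$distance_upstream_tss >= 0, na.rm = TRUE))
  expect_true(all(is.na(ann$distance_upstream_tss[!ann$upstream])))
})

test_that("probes map to exactly one gene each, many-to-one onto genes", {
  cfg <- sim_config(features_per_modality = c(mrna = 10, mirna = 5, lncrna = 5,
                                              methylation = 100), seed = 3)
  ann <- generate_probe_annotation(cfg, seed = 3)
  expect_equal(length(ann$gene_id), 100)
  expect_lte(length(unique(ann$gene_id)), round(100 / 3))
  expect_gt(max(table(ann$gene_id)), 1)
})

test_that("NB count marginals match the configured dispersion (method of moments)", {
  cfg <- sim_config(n_patients = 1500,
                    features_per_modality = c(mrna = 150, mirna = 5, lncrna = 5,
                                              methylation = 5),
                    frac_informative = 0, subtype_shift = 0, missing_rate = 0,
                    elevated_missing_frac = 0, dispersion = 0.2, seed = 17)
  g <- generate_dataset(cfg)
  cc <- g$dataset$counts$mrna
  mu <- colMeans(cc)
  v <- apply(cc, 2, var)
  # var = mu + a mu^2 (library-size spread inflates the estimate slightly)
  a_hat <- median((v - mu) / mu^2)
  expect_lt(abs(a_hat - 0.2), 0.08)
})

test_that("planted subtypes are separable on informative features", {
  g <- small_gen()
  ds <- g$dataset
  inf <- g$truth$informative_features$mrna
  X <- ds$modalities$mrna[, inf]
  X[is.na(X)] <- 0
  X <- scale(X)
  s_true <- silhouette_width(X, g$truth$subtype_labels)
  set.seed(1)
  s_rand <- mean(replicate(5, silhouette_width(X, sample(g$truth$subtype_labels))))
  expect_gt(s_true, s_rand)
})

test_that("datasets round-trip through the TSV/JSON writers", {
  cfg <- sim_config(n_patients = 40,
                    features_per_modality = c(mrna = 20, mirna = 10,
                                              lncrna = 10, methylation = 30),
                    seed = 5)
  g <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(g$dataset, dir, truth = g$truth)
  back <- read_dataset(dir)
  expect_equal(back$modalities$mrna, g$dataset$modalities$mrna, tolerance = 1e-12)
  expect_equal(back$counts$mrna, g$dataset$counts$mrna)
  expect_identical(back$patient_ids, g$dataset$patient_ids)
  expect_equal(back$survival$time_days, g$dataset$survival$time_days, tolerance = 1e-12)
  expect_identical(back$cohort, g$dataset$cohort)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(censoring_rate = 1.5), "censoring_rate")
  expect_error(sim_config(n_latent = 2, n_survival_latents = 3), "n_survival_latents")
  expect_error(sim_config(signal_allocation = list(proteomics = 1L)), "proteomics")
})
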