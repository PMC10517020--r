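# Preprocessing: filters, scaler, methylation probe pipeline, beta -> M,
# clinical encoding, leakage freedom and alignment.

test_that("missingness filter is strict at the 20% boundary", {
  # 5 features x 10 patients with {0,1,2,3,10} missing entries each
  m <- matrix(1, 10, 5, dimnames = list(NULL, paste0("f", 1:5)))
  m[1, 2] <- NA
  m[1:2, 3] <- 0
  m[1:3, 4] <- NA
  m[, 5] <- 0
  out <- filter_features_by_missingness(m)
  expect_identical(colnames(out), c("f1", "f2", "f3"))  # 30% and 100% removed
  expect_error(filter_features_by_missingness(matrix(0, 4, 2), modality = "mirna"),
               "mirna")
})

test_that("follow-up filter removes times of 0 and 1 day from all components", {
  g <- small_gen()
  ds <- subset_patients(g$dataset, 1:100)
  ds$survival$time_days[c(3, 10, 20, 21, 40, 77, 99)] <- c(1, 1, 0.5, 1, 1, 0.9, 1)
  out <- filter_patients_by_followup(ds)
  expect_equal(n_patients(out), 93)
  expect_equal(nrow(out$modalities$mrna), 93)
  expect_equal(nrow(out$clinical), 93)
  expect_equal(length(out$cohort), 93)
  expect_true(all(out$survival$time_days > 1))
  # all times > 1 day: identity
  expect_identical(filter_patients_by_followup(out), out)
  # explicit boundary: {0, 1, 2, 500}
  ds2 <- subset_patients(g$dataset, 1:4)
  ds2$survival$time_days <- c(0.5, 1, 2, 500)
  expect_equal(filter_patients_by_followup(ds2)$survival$time_days, c(2, 500))
})

test_that("scaler: population-SD z-scoring, median imputation, round trip", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 4, 10))
  sc <- fit_scaler(m)
  z <- apply_scaler(m, sc)
  # population-SD convention (ddof 0): SD of {1,2,3} is sqrt(2/3), so the
  # centered column {-1,0,1} scales to +/- sqrt(3/2)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1) * sqrt(3 / 2))
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, function(x) mean(x^2) - mean(x)^2), c(a = 1, b = 1),
               tolerance = 1e-12)
  # test value equal to the train mean maps to 0
  z2 <- apply_scaler(cbind(a = 2, b = 6), sc)
  expect_equal(unname(z2[1, ]), c(0, 0))
  # median imputation before scoring
  z3 <- apply_scaler(cbind(a = NA_real_, b = 4), sc)
  expect_equal(unname(z3[1, "a"]), unname(z[2, "a"]))  # median of {1,2,3} is 2
  # round trip within 1e-10
  test_m <- cbind(a = rnorm(5, 2, 3), b = rnorm(5, 6, 1))
  back <- apply_scaler(apply_scaler(test_m, sc), sc, inverse = TRUE)
  expect_equal(back, test_m, tolerance = 1e-10)
})

test_that("zero-variance features are dropped with a warning", {
  m <- cbind(a = c(1, 2, 3), flat = c(5, 5, 5))
  expect_warning(sc <- fit_scaler(m), "zero-variance")
  expect_identical(sc$features, "a")
  expect_equal(colnames(apply_scaler(m, sc)), "a")
})

test_that("scaler round-trips through JSON serialization", {
  sc <- fit_scaler(cbind(a = c(1, 2, 3), b = c(4, 4, 10)))
  path <- withr::local_tempfile(fileext = ".json")
  write_scaler(sc, path)
  sc2 <- read_scaler(path)
  expect_equal(sc2$center, sc$center)
  expect_equal(sc2$scale, sc$scale)
  expect_equal(sc2$median, sc$median)
})

test_that("methylation probe filter applies missingness, island/TSS and variance in order", {
  set.seed(4)
  n <- 20
  planted_sd <- seq(0.01, 0.2, length.out = 10)
  beta <- sapply(planted_sd, function(s) plogis(rnorm(n, 0, 4 * s)))
  colnames(beta) <- paste0("cg", 1:10)
  ann <- data.frame(probe_id = paste0("cg", 1:10), gene_id = "G1",
                    in_cpg_island = TRUE, upstream = TRUE,
                    distance_upstream_tss = 100L)
  # probe 1: 25% missing -> removed regardless of annotation
  beta_m <- beta
  beta_m[1:5, 1] <- NA
  out <- filter_methylation_probes(beta_m, ann, top_variance = 100)
  expect_false("cg1" %in% colnames(out))
  # boundary: 1500 bp retained, 1501 bp removed; downstream sentinel removed
  ann2 <- ann
  ann2$distance_upstream_tss <- c(1500L, 1501L, rep(100L, 8))
  ann2$upstream[3] <- FALSE
  ann2$distance_upstream_tss[3] <- NA
  out2 <- filter_methylation_probes(beta, ann2, top_variance = 100)
  expect_true("cg1" %in% colnames(out2))
  expect_false("cg2" %in% colnames(out2))
  expect_false("cg3" %in% colnames(out2))
  # top-k by variance equals the k largest sample variances (sort oracle)
  v <- apply(beta, 2, var)
  out3 <- filter_methylation_probes(beta, ann, top_variance = 4)
  expect_setequal(colnames(out3), names(sort(v, decreasing = TRUE))[1:4])
})

test_that("methylation filter order is load-bearing (adversarial fixture)", {
  # the highest-variance probe is out of scope: variance-first would keep it
  set.seed(5)
  beta <- cbind(cg1 = plogis(rnorm(30, 0, 3)),   # huge variance, NOT in island
                cg2 = plogis(rnorm(30, 0, 0.5)),
                cg3 = plogis(rnorm(30, 0, 0.1)))
  ann <- data.frame(probe_id = paste0("cg", 1:3), gene_id = "G1",
                    in_cpg_island = c(FALSE, TRUE, TRUE), upstream = TRUE,
                    distance_upstream_tss = 100L)
  pinned <- filter_methylation_probes(beta, ann, top_variance = 1)
  expect_identical(colnames(pinned), "cg2")
  # permuted order (variance before annotation) keeps cg1 instead
  v <- apply(beta, 2, var)
  top_first <- names(sort(v, decreasing = TRUE))[1]
  expect_identical(top_first, "cg1")
  expect_false(identical(colnames(pinned), top_first))
})

test_that("beta -> M transform: closed forms, monotonicity, Gaussianity", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  b <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(beta_to_m(b)) > 0))
  # clamping keeps the boundary finite
  expect_true(is.finite(beta_to_m(0)) && is.finite(beta_to_m(1)))
  # logit-normal betas give exactly Gaussian M-values (the generator's
  # construction): moments recover mu, sigma
  set.seed(6)
  mu <- 1.3; sigma <- 0.7
  g <- rnorm(10000, mu, sigma)
  m <- beta_to_m(1 / (1 + 2^(-g)))
  expect_lt(abs(mean(m) - mu), 0.03)
  expect_lt(abs(sd(m) - sigma), 0.03)
  expect_gt(stats::shapiro.test(m[1:5000])$p.value, 0.01)
})

test_that("clinical encoding: volume product, ordinal staging, default 11 columns", {
  g <- small_gen()
  clin <- g$dataset$clinical
  enc <- fit_clinical_encoder(clin)
  X <- encode_clinical(clin, enc)
  expect_equal(ncol(X), 11)
  # tumor volume = product of the three dimensions
  expect_equal(compute_tumor_volume(data.frame(tumor_dim1 = 1, tumor_dim2 = 1,
                                               tumor_dim3 = 0.5)), 0.5)
  # stage collapse: "Stage 3A" -> 3, "T1a" -> 1, "N2" -> 2, "M1b" -> 1
  expect_equal(stage_to_ordinal(c("Stage 3A", "Stage 1B", "Stage 4", "T1a", "N2", "M1b")),
               c(3L, 1L, 4L, 1L, 2L, 1L))
  # continuous columns are z-scored with train stats
  expect_lt(abs(mean(X[, "age"])), 1e-10)
})

test_that("missing-indicator mode activates only when values are missing", {
  g <- small_gen()
  clin <- g$dataset$clinical
  complete <- clin
  for (v in names(complete)) {
    if (is.numeric(complete[[v]])) {
      complete[[v]][is.na(complete[[v]])] <- median(complete[[v]], na.rm = TRUE)
    } else {
      lv <- names(sort(table(complete[[v]]), decreasing = TRUE))[1]
      complete[[v]][is.na(complete[[v]])] <- lv
    }
  }
  enc <- fit_clinical_encoder(complete, missing_indicators = TRUE)
  X <- encode_clinical(complete, enc)
  miss_cols <- grep("_missing$", colnames(X))
  expect_gt(length(miss_cols), 0)
  expect_equal(sum(X[, miss_cols]), 0)
  # with the real (missing-containing) table the indicators light up
  X2 <- encode_clinical(clin, enc)
  expect_gt(sum(X2[, grep("_missing$", colnames(X2))]), 0)
})

test_that("unknown categorical levels map to the missing/reference level", {
  g <- small_gen()
  clin <- g$dataset$clinical[1:5, ]
  enc <- fit_clinical_encoder(g$dataset$clinical)
  clin$sex[1] <- "Unknown"
  X <- encode_clinical(clin, enc)
  expect_equal(X[1, "sex_Female"], 0)
})

test_that("fitted preprocessing state is a pure function of training data", {
  g <- small_gen()
  train <- subset_patients(g$dataset, 1:200)
  test1 <- subset_patients(g$dataset, 201:300)
  # perturb the test matrix heavily; the fitted state must not move
  test2 <- test1
  test2$modalities$mrna <- test1$modalities$mrna * 5 + 3
  sc <- fit_scaler(train$modalities$mrna)
  expect_identical(sc, fit_scaler(train$modalities$mrna))
  z1 <- apply_scaler(test1$modalities$mrna, sc)
  z2 <- apply_scaler(test2$modalities$mrna, sc)
  # same frozen affine map applied to both: z2 - 5*z1 is constant per column
  d <- z2 - 5 * z1
  d[is.na(test1$modalities$mrna[, colnames(z1)])] <- NA  # imputed cells differ
  spread <- apply(d, 2, function(x) diff(range(x, na.rm = TRUE)))
  expect_lt(max(spread), 1e-8)
})
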