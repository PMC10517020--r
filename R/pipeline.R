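# End-to-end experiment orchestration: stratified train/test splits,
# train-fitted preprocessing + feature screening + dimensionality reduction,
# elastic-net Cox fitting, held-out C-index evaluation across independent
# runs, modality-combination sweeps and between-configuration tests.
#
# Everything fitted (filters, scalers, selected features, encoder weights,
# PCA rotations, Cox coefficients) is a pure function of the training
# split: `fit_pipeline_state()` sees only training patients, and
# `apply_pipeline_state()` replays the frozen state on any aligned dataset.

BIO_MODALITIES <- c("mrna", "mirna", "lncrna", "methylation")

#' Experiment configuration
#'
#' @param modalities subset of `c("mrna","mirna","lncrna","methylation",
#'   "clinical")`. Clinical data never pass through the autoencoder; they
#'   are encoded and appended after the embedding.
#' @param integration `"early"` (one autoencoder on the concatenated
#'   selected features) or `"late"` (one per modality, embeddings
#'   concatenated).
#' @param train_cohort train on `"both"` cohorts or restrict to `"A"`/`"B"`.
#' @param eval_cohort evaluate on `"both"`, `"A"` or `"B"` test patients.
#' @param dr_method `"lfs_ae"` (screening + autoencoder, the default
#'   pipeline), `"lfs_only"`, `"pca"` (train-fitted components matched to
#'   the embedding width) or `"ae_only"` (autoencoder on a variance-capped
#'   feature set, no screening).
#' @param n_runs number of independent stratified resplits.
#' @param train_fraction training fraction of each split.
#' @param seeds integer seeds, one per run (defaults to `1:n_runs`).
#' @param lfs_caps named per-modality top-k caps (full-scale defaults: 500
#'   for mRNA/methylation, 300 for lncRNA/miRNA).
#' @param bottleneck_ratio embedding width as a fraction of the
#'   autoencoder input width (the published shapes are all 10:1).
#' @param top_variance methylation variance-filter cap.
#' @param ae hyperparameters forwarded to [encoder_spec()] (activation,
#'   noise_type, noise_level, max_epochs, patience, batch_size,
#'   learning_rate).
#' @param alpha,n_folds elastic-net mixing weight and CV folds.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(modalities = c("mrna", "mirna", "lncrna", "methylation", "clinical"),
                              integration = c("early", "late"),
                              train_cohort = c("both", "A", "B"),
                              eval_cohort = c("both", "A", "B"),
                              dr_method = c("lfs_ae", "lfs_only", "pca", "ae_only"),
                              n_runs = 5L, train_fraction = 0.8, seeds = NULL,
                              lfs_caps = c(mrna = 500L, methylation = 500L,
                                           lncrna = 300L, mirna = 300L),
                              bottleneck_ratio = 0.1,
                              top_variance = 25000L,
                              ae = list(),
                              alpha = 0.5, n_folds = 5L) {
  integration <- match.arg(integration)
  train_cohort <- match.arg(train_cohort)
  eval_cohort <- match.arg(eval_cohort)
  dr_method <- match.arg(dr_method)
  ok <- c(BIO_MODALITIES, "clinical")
  if (!all(modalities %in% ok)) stopf("unknown modality: %s",
                                      paste(setdiff(modalities, ok), collapse = ", "))
  if (length(modalities) == 0) stopf("at least one modality required")
  if (is.null(seeds)) seeds <- seq_len(n_runs)
  if (length(seeds) != n_runs) stopf("need %d seeds", n_runs)
  ae_defaults <- list(activation = "sigmoid", noise_type = "zeros",
                      noise_level = 0.3, max_epochs = 100L, patience = 5L,
                      batch_size = 32L, learning_rate = 0.001)
  ae <- utils::modifyList(ae_defaults, ae)
  structure(list(modalities = modalities, integration = integration,
                 train_cohort = train_cohort, eval_cohort = eval_cohort,
                 dr_method = dr_method, n_runs = as.integer(n_runs),
                 train_fraction = train_fraction, seeds = as.integer(seeds),
                 lfs_caps = lfs_caps, bottleneck_ratio = bottleneck_ratio,
                 top_variance = as.integer(top_variance), ae = ae,
                 alpha = alpha, n_folds = as.integer(n_folds)),
            class = "experiment_config")
}

#' Stratified patient-level train/test split
#'
#' Stratifies by the event indicator crossed with the cohort label so both
#' appear in both parts; deterministic per seed.
#'
#' @param dataset a `multiomics_dataset`.
#' @param fraction training fraction in (0,1).
#' @param seed RNG seed.
#' @return list with `train` and `test` datasets (disjoint, union = all).
#' @export
split_train_test <- function(dataset, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  strata <- interaction(dataset$survival$event != 0, dataset$cohort, drop = TRUE)
  train_idx <- integer(0)
  with_seed(seed, {
    for (s in levels(strata)) {
      idx <- which(strata == s)
      n_tr <- round(fraction * length(idx))
      if (n_tr == 0 || n_tr == length(idx)) {
        stopf("stratum '%s' (n = %d) is too small to split", s, length(idx))
      }
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
  })
  train_idx <- sort(train_idx)
  list(train = subset_patients(dataset, train_idx),
       test = subset_patients(dataset, setdiff(seq_len(n_patients(dataset)), train_idx)))
}

# Fit every data-dependent transform on the training split only.
fit_pipeline_state <- function(train, config, seed) {
  st <- list(config = config, seed = seed)
  bio <- intersect(config$modalities, BIO_MODALITIES)
  time <- train$survival$time_days
  event <- train$survival$event

  st$scalers <- list()
  st$selected <- list()
  train_scaled <- list()
  for (m in bio) {
    mat <- train$modalities[[m]]
    if (m == "methylation") {
      mat <- filter_methylation_probes(mat, train$probe_annotation,
                                       top_variance = config$top_variance)
    } else {
      mat <- filter_features_by_missingness(mat, modality = m)
    }
    scaler <- suppressWarnings(fit_scaler(mat))
    z <- apply_scaler(mat, scaler)
    if (config$dr_method %in% c("lfs_ae", "lfs_only", "pca")) {
      screen <- cox_screen(z, time, event)
      sel <- suppressWarnings(select_top_k(screen, config$lfs_caps[[m]]))
      st$screens[[m]] <- screen
    } else {  # ae_only: variance cap instead of screening, desk-scale guard
      k <- min(ncol(z), 4L * config$lfs_caps[[m]])
      v <- apply(mat[, scaler$features, drop = FALSE], 2, stats::var, na.rm = TRUE)
      sel <- scaler$features[order(v, decreasing = TRUE)][seq_len(k)]
    }
    st$scalers[[m]] <- scaler
    st$selected[[m]] <- sel
    train_scaled[[m]] <- z[, sel, drop = FALSE]
  }

  # dimensionality reduction on the selected training features
  if (length(bio) > 0 && config$dr_method != "lfs_only") {
    seed_ae <- child_seed(seed, "ae")
    if (config$integration == "early") {
      Xb <- do.call(cbind, train_scaled)
      target <- max(1L, ceiling(config$bottleneck_ratio * ncol(Xb)))
      st$reducer <- fit_reducer(Xb, target, config, seed_ae)
    } else {
      st$reducer <- lapply(seq_along(bio), function(i) {
        m <- bio[i]
        target <- max(1L, ceiling(config$bottleneck_ratio * ncol(train_scaled[[m]])))
        fit_reducer(train_scaled[[m]], target, config, child_seed(seed_ae, m))
      })
      names(st$reducer) <- bio
    }
  }

  if ("clinical" %in% config$modalities) {
    st$clin_encoder <- fit_clinical_encoder(train$clinical)
  }

  X_train <- assemble_features(st, train)
  st$final_scaler <- suppressWarnings(fit_scaler(X_train))
  X_train <- apply_scaler(X_train, st$final_scaler)
  st$cox_fit <- fit_elastic_net_cox(X_train, time, event, alpha = config$alpha,
                                    n_folds = config$n_folds,
                                    seed = child_seed(seed, "cv"))
  st
}

fit_reducer <- function(X, target_dim, config, seed) {
  if (config$dr_method == "pca") {
    k <- min(target_dim, ncol(X), nrow(X) - 1)
    pr <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
    list(kind = "pca", center = pr$center, rotation = pr$rotation)
  } else {
    spec <- encoder_spec(input_dim = ncol(X), bottleneck_dim = target_dim,
                         activation = config$ae$activation,
                         noise_type = config$ae$noise_type,
                         noise_level = config$ae$noise_level,
                         learning_rate = config$ae$learning_rate,
                         max_epochs = config$ae$max_epochs,
                         patience = config$ae$patience,
                         batch_size = config$ae$batch_size, seed = seed)
    list(kind = "ae", model = train_autoencoder(spec, X))
  }
}

apply_reducer <- function(red, X) {
  if (red$kind == "pca") {
    emb <- sweep(X, 2, red$center) %*% red$rotation
    colnames(emb) <- sprintf("pc%03d", seq_len(ncol(emb)))
    emb
  } else {
    encode(red$model, X)
  }
}

# Replay the frozen state on any aligned dataset: returns the standardized
# survival-model input matrix (embeddings/features + encoded clinical).
apply_pipeline_state <- function(state, dataset, standardize = TRUE) {
  X <- assemble_features(state, dataset)
  if (standardize) X <- apply_scaler(X, state$final_scaler)
  X
}

assemble_features <- function(st, dataset) {
  config <- st$config
  bio <- intersect(config$modalities, BIO_MODALITIES)
  parts <- list()
  scaled <- lapply(bio, function(m) {
    z <- apply_scaler(dataset$modalities[[m]], st$scalers[[m]])
    z[, st$selected[[m]], drop = FALSE]
  })
  names(scaled) <- bio
  if (length(bio) > 0) {
    if (config$dr_method == "lfs_only") {
      feats <- do.call(cbind, scaled)
      colnames(feats) <- unlist(lapply(bio, function(m) paste0(m, ".", st$selected[[m]])))
      parts$bio <- feats
    } else if (config$integration == "early") {
      parts$bio <- apply_reducer(st$reducer, do.call(cbind, scaled))
    } else {
      embs <- lapply(bio, function(m) {
        e <- apply_reducer(st$reducer[[m]], scaled[[m]])
        colnames(e) <- paste0(m, ".", colnames(e))
        e
      })
      parts$bio <- do.call(cbind, embs)
    }
  }
  if ("clinical" %in% config$modalities) {
    parts$clinical <- encode_clinical(dataset$clinical, st$clin_encoder)
  }
  X <- do.call(cbind, parts)
  rownames(X) <- dataset$patient_ids
  X
}

#' Run one experiment configuration across independent resplits
#'
#' For each seed: stratified 80/20 split, train-only preprocessing and
#' feature screening, dimensionality reduction, clinical encoding,
#' elastic-net Cox fit, and Harrell C-index on the held-out test patients
#' (restricted to `eval_cohort`). Any stage failure aborts that run with a
#' stage-tagged diagnostic; remaining seeds still run and the report flags
#' incomplete runs.
#'
#' @param config an [experiment_config()].
#' @param dataset a `multiomics_dataset` (the follow-up filter is applied
#'   up front).
#' @param keep_states if `TRUE`, the fitted per-run states are kept on the
#'   report (needed for subtype discovery).
#' @return a `run_report` with per-run C-indices, mean and SD.
#' @export
run_configuration <- function(config, dataset, keep_states = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dataset <- filter_patients_by_followup(dataset)
  cidx <- rep(NA_real_, config$n_runs)
  states <- vector("list", config$n_runs)
  errors <- character(config$n_runs)
  for (r in seq_len(config$n_runs)) {
    seed <- config$seeds[r]
    res <- tryCatch({
      sp <- split_train_test(dataset, config$train_fraction,
                             seed = child_seed(seed, "split"))
      train <- sp$train
      if (config$train_cohort != "both") {
        train <- subset_patients(train, train$cohort == config$train_cohort)
      }
      state <- fit_pipeline_state(train, config, seed)
      test <- sp$test
      if (config$eval_cohort != "both") {
        test <- subset_patients(test, test$cohort == config$eval_cohort)
      }
      X_test <- apply_pipeline_state(state, test)
      risk <- predict_risk(state$cox_fit, X_test)
      ci <- harrell_cindex(risk, test$survival$time_days, test$survival$event)
      list(ci = ci$c_index, state = state)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[r] <- conditionMessage(res)
      omicsurv_log("run ", r, " failed: ", errors[r], verbose = TRUE)
    } else {
      cidx[r] <- res$ci
      if (keep_states) states[[r]] <- res$state
    }
  }
  ok <- !is.na(cidx)
  structure(list(config = config, c_indices = cidx,
                 mean = mean(cidx[ok]), sd = stats::sd(cidx[ok]),
                 errors = errors, incomplete = any(!ok),
                 states = if (keep_states) states),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report [%s | %s | dr=%s]: mean C-index %.3f +/- %.3f over %d run(s)\n",
              paste(x$config$modalities, collapse = "+"), x$config$integration,
              x$config$dr_method, x$mean,
              if (is.na(x$sd)) 0 else x$sd, sum(!is.na(x$c_indices))))
  if (x$incomplete) cat("  (incomplete: ", sum(is.na(x$c_indices)), " run(s) failed)\n", sep = "")
  invisible(x)
}

#' Enumerate non-empty modality subsets
#' @param modalities character vector of available modalities.
#' @return list of character vectors (2^m - 1 subsets).
#' @export
modality_subsets <- function(modalities) {
  m <- length(modalities)
  subsets <- list()
  for (mask in seq_len(2^m - 1)) {
    subsets[[mask]] <- modalities[bitwAnd(mask, 2^(seq_len(m) - 1)) != 0]
  }
  subsets
}

#' Sweep all modality combinations
#'
#' Runs [run_configuration()] for every non-empty subset of the available
#' modalities (31 for all five) and returns a table sorted by mean C-index.
#'
#' @param dataset a `multiomics_dataset`.
#' @param base_config an [experiment_config()] supplying everything except
#'   the modality set.
#' @param modalities modalities to sweep over.
#' @param both_integrations also run the late-integration variant for
#'   subsets with two or more biological modalities.
#' @return data.frame with columns `modalities`, `integration`,
#'   `mean_c_index`, `sd_c_index`, sorted by descending mean.
#' @export
sweep_modality_combinations <- function(dataset, base_config,
                                        modalities = base_config$modalities,
                                        both_integrations = FALSE) {
  if (length(modalities) < 2) stopf("need at least 2 modalities to sweep")
  subsets <- modality_subsets(modalities)
  rows <- list()
  for (sub in subsets) {
    integrations <- "early"
    if (both_integrations && length(intersect(sub, BIO_MODALITIES)) >= 2) {
      integrations <- c("early", "late")
    }
    for (integ in integrations) {
      cfg <- base_config
      cfg$modalities <- sub
      cfg$integration <- integ
      rep <- run_configuration(cfg, dataset)
      rows[[length(rows) + 1]] <- data.frame(
        modalities = paste(sub, collapse = "+"), integration = integ,
        mean_c_index = rep$mean, sd_c_index = rep$sd,
        n_runs = sum(!is.na(rep$c_indices)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(-out$mean_c_index), ]
}

#' Compare two run reports by Welch t-test
#'
#' Two-sample two-sided Welch t-test on the per-run C-index lists. When
#' both lists are (numerically) constant the test is undefined; the result
#' is flagged `degenerate` with p = 1 for identical means and p = 0
#' otherwise.
#'
#' @param report_a,report_b `run_report`s (or bare numeric vectors of
#'   per-run C-indices) with at least 2 runs each.
#' @return list with `p_value`, `t`, `degenerate`.
#' @export
compare_configurations <- function(report_a, report_b) {
  a <- if (inherits(report_a, "run_report")) report_a$c_indices else report_a
  b <- if (inherits(report_b, "run_report")) report_b$c_indices else report_b
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stopf("need at least 2 runs per configuration")
  if (stats::var(a) < 1e-24 && stats::var(b) < 1e-24) {
    return(list(p_value = if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0,
                t = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(p_value = tt$p.value, t = unname(tt$statistic), degenerate = FALSE)
}

#' Grid-search autoencoder variants by downstream survival performance
#'
#' For every grid row, runs the pipeline on each individual biological
#' modality and on the multimodal combination, and reports the mean test
#' C-index across those runs — the ranking criterion used to choose the
#' final denoising scheme.
#'
#' @param dataset a `multiomics_dataset`.
#' @param base_config an [experiment_config()].
#' @param grid data.frame like [default_encoder_grid()].
#' @return data.frame sorted by descending mean C-index.
#' @export
grid_search_autoencoders <- function(dataset, base_config,
                                     grid = default_encoder_grid()) {
  bio <- intersect(base_config$modalities, BIO_MODALITIES)
  eval_sets <- c(lapply(bio, function(m) c(m, intersect(base_config$modalities, "clinical"))),
                 list(base_config$modalities))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base_config
    cfg$ae$noise_type <- grid$noise_type[i]
    cfg$ae$noise_level <- grid$noise_level[i]
    cfg$ae$activation <- grid$activation[i]
    cis <- vapply(eval_sets, function(ms) {
      c2 <- cfg; c2$modalities <- ms
      run_configuration(c2, dataset)$mean
    }, numeric(1))
    data.frame(noise_type = grid$noise_type[i], noise_level = grid$noise_level[i],
               activation = grid$activation[i], mean_c_index = mean(cis),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$mean_c_index), ]
}
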