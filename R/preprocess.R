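# Preprocessing: train-fitted filters, scaling, imputation, the methylation
# probe pipeline, the beta -> M transform, and clinical encoding. Every
# statistic applied to test data is a pure function of training data.

#' Remove features with excessive zero-or-missing values
#'
#' A feature is removed when its fraction of zero-or-missing values across
#' patients is strictly greater than `threshold` ("more than 20%" is read as
#' strict: exactly 20% is retained). Feature order is preserved. Applies to
#' the expression modalities (mRNA, miRNA, lncRNA).
#'
#' @param matrix patients x features numeric matrix; `NA` and `0` both count
#'   as missing.
#' @param threshold maximum tolerated zero-or-missing fraction.
#' @param modality name used in the error message when nothing survives.
#' @return the matrix restricted to retained features.
#' @export
filter_features_by_missingness <- function(matrix, threshold = 0.20,
                                           modality = "modality") {
  frac <- colMeans(is.na(matrix) | matrix == 0)  # TRUE | NA is TRUE, so NA-safe
  keep <- frac <= threshold
  if (!any(keep)) stopf("empty-modality error: all features of '%s' exceed the %.0f%% zero/missing threshold",
                        modality, 100 * threshold)
  matrix[, keep, drop = FALSE]
}

#' Remove patients with follow-up of one day or less
#'
#' Patients with survival time of 0 or 1 day are removed from every dataset
#' component simultaneously.
#'
#' @param dataset a `multiomics_dataset`.
#' @return the filtered dataset.
#' @export
filter_patients_by_followup <- function(dataset) {
  keep <- dataset$survival$time_days > 1
  if (!any(keep)) stopf("no patients remain after the follow-up filter")
  if (all(keep)) return(dataset)
  subset_patients(dataset, keep)
}

#' Fit a median-imputing z-scaler on training data
#'
#' Records, per feature: the training median (used to impute missing
#' values), and the post-imputation training mean and population standard
#' deviation (ddof 0). Zero-variance features are dropped with a warning.
#'
#' @param matrix training patients x features matrix (may contain `NA`).
#' @return a `scaler_state` with elements `features`, `median`, `center`,
#'   `scale`.
#' @export
fit_scaler <- function(matrix) {
  med <- apply(matrix, 2, stats::median, na.rm = TRUE)
  imp <- impute_columns(matrix, med)
  ctr <- colMeans(imp)
  n <- nrow(imp)
  sdv <- sqrt(colMeans(imp^2) - ctr^2)
  sdv[sdv < 0] <- 0  # numerical guard
  keep <- sdv > 1e-12
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance feature(s)", sum(!keep)), call. = FALSE)
  }
  structure(list(features = colnames(matrix)[keep], median = med[keep],
                 center = ctr[keep], scale = sdv[keep]),
            class = "scaler_state")
}

impute_columns <- function(matrix, med) {
  na_idx <- which(is.na(matrix), arr.ind = TRUE)
  if (nrow(na_idx)) matrix[na_idx] <- med[na_idx[, 2]]
  matrix
}

#' Apply (or invert) a fitted scaler
#'
#' Imputes missing values with the training median, then z-scores with the
#' training mean/SD. Columns the scaler dropped are dropped here too.
#'
#' @param matrix patients x features matrix.
#' @param scaler a `scaler_state` from [fit_scaler()].
#' @param inverse if `TRUE`, undo the z-scoring (imputation is not
#'   invertible; missing entries come back as the training median).
#' @return the transformed matrix restricted to the scaler's features.
#' @export
apply_scaler <- function(matrix, scaler, inverse = FALSE) {
  stopifnot(inherits(scaler, "scaler_state"))
  miss <- setdiff(scaler$features, colnames(matrix))
  if (length(miss)) stopf("matrix lacks %d feature(s) the scaler was fitted on", length(miss))
  m <- matrix[, scaler$features, drop = FALSE]
  if (inverse) {
    return(sweep(sweep(m, 2, scaler$scale, "*"), 2, scaler$center, "+"))
  }
  m <- impute_columns(m, scaler$median)
  sweep(sweep(m, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' Serialize / restore a scaler for audit
#' @param scaler a `scaler_state`.
#' @param path JSON file path.
#' @return `path` (write) or a `scaler_state` (read).
#' @export
write_scaler <- function(scaler, path) {
  jsonlite::write_json(unclass(scaler), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(features = s$features,
                 median = stats::setNames(s$median, s$features),
                 center = stats::setNames(s$center, s$features),
                 scale = stats::setNames(s$scale, s$features)),
            class = "scaler_state")
}

#' Three-step methylation probe filter
#'
#' Applies, in this fixed order: (1) drop probes with more than
#' `missing_threshold` missing values (strict, as for expression features);
#' (2) keep only probes in CpG islands within `max_upstream` base pairs
#' upstream of the TSS (inclusive of the boundary; downstream probes are
#' excluded); (3) keep the `top_variance` probes with the highest beta-value
#' variance (missing entries excluded pairwise). If fewer than
#' `top_variance` probes survive steps 1-2, all survivors are kept. The
#' order is load-bearing: variance ranks computed before the annotation
#' filter would admit different probes.
#'
#' @param beta patients x probes matrix of beta values (may contain `NA`).
#' @param annotation probe annotation covering all probes (see
#'   [generate_probe_annotation()]).
#' @param missing_threshold maximum tolerated missing fraction.
#' @param max_upstream maximum distance upstream of the TSS (bp).
#' @param top_variance number of highest-variance probes retained.
#' @return the beta matrix restricted to retained probes.
#' @export
filter_methylation_probes <- function(beta, annotation,
                                      missing_threshold = 0.20,
                                      max_upstream = 1500,
                                      top_variance = 25000) {
  probes <- colnames(beta)
  if (!all(probes %in% annotation$probe_id)) {
    stopf("annotation does not cover all probes")
  }
  # step 1: missingness (NA only -- beta of 0 is a legitimate value)
  frac_na <- colMeans(is.na(beta))
  keep <- frac_na <= missing_threshold
  # step 2: CpG island within max_upstream bp upstream of the TSS
  ann <- annotation[match(probes, annotation$probe_id), ]
  in_scope <- ann$in_cpg_island & ann$upstream &
    !is.na(ann$distance_upstream_tss) & ann$distance_upstream_tss <= max_upstream
  keep <- keep & in_scope
  if (!any(keep)) stopf("empty-modality error: no methylation probes survive the filters")
  beta <- beta[, keep, drop = FALSE]
  # step 3: top variance among survivors
  if (ncol(beta) > top_variance) {
    v <- apply(beta, 2, stats::var, na.rm = TRUE)
    ord <- order(v, decreasing = TRUE)
    beta <- beta[, sort(ord[seq_len(top_variance)]), drop = FALSE]
  }
  beta
}

#' Beta to M-value transform
#'
#' `M = log2(beta / (1 - beta))`, the log2-odds of methylation. Betas are
#' clamped to `[eps, 1 - eps]` first so boundary values stay finite. The
#' transform is monotone increasing with `M(0.5) = 0`.
#'
#' @param beta numeric vector/matrix of beta values.
#' @param eps clamping margin.
#' @return M-values with the same shape.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

# ---- clinical encoding -----------------------------------------------------

# Collapse a staging string to its ordinal main stage: "Stage 3A" -> 3,
# "T2b" -> 2, "N1" -> 1, "M1a" -> 1. NA-safe.
stage_to_ordinal <- function(x) {
  out <- suppressWarnings(as.integer(sub(".*?([0-9]).*", "\\1", as.character(x))))
  out[is.na(x)] <- NA_integer_
  out
}

clinical_continuous <- c("age", "tumor_volume", "pack_years")
clinical_ordinal <- c("pathological_stage", "staging_t", "staging_n", "staging_m")
# categorical -> (levels one-hot encoded beyond the reference, has missing level)
clinical_categorical <- list(
  sex = list(ref = "Male", levels = "Female", missing_level = FALSE),
  primary_diagnosis = list(ref = "Adenocarcinoma", levels = "Squamous cell carcinoma",
                           missing_level = FALSE),
  prior_malignancy = list(ref = "No", levels = "Yes", missing_level = FALSE),
  synchronous_malignancy = list(ref = "No", levels = "Yes", missing_level = TRUE))

# Tumor volume: simple product of the three recorded dimensions (cm^3).
compute_tumor_volume <- function(clinical) {
  clinical$tumor_dim1 * clinical$tumor_dim2 * clinical$tumor_dim3
}

#' Fit the clinical encoder on training patients
#'
#' Captures training medians/means/SDs for the continuous features (age,
#' tumor volume = product of the three recorded dimensions, pack-years) and
#' training medians for the ordinal staging codes, so the encoding of test
#' patients is a pure function of training data.
#'
#' By default the encoding emits exactly 11 numeric columns (3 continuous,
#' 4 ordinal staging codes, 4 binary indicators), matching the published
#' 160 + 11 = 171-wide survival-model input; set
#' `missing_indicators = TRUE` to additionally emit explicit missing-level
#' columns for the variables whose schema reports missing samples.
#'
#' @param clinical training clinical table (11-feature schema).
#' @param missing_indicators emit explicit missingness columns.
#' @return a `clinical_encoder`.
#' @export
fit_clinical_encoder <- function(clinical, missing_indicators = FALSE) {
  cont <- data.frame(age = clinical$age,
                     tumor_volume = compute_tumor_volume(clinical),
                     pack_years = clinical$pack_years)
  cont_stats <- lapply(cont, function(x) {
    med <- stats::median(x, na.rm = TRUE)
    xi <- ifelse(is.na(x), med, x)
    list(median = med, center = mean(xi), scale = sqrt(mean(xi^2) - mean(xi)^2))
  })
  ord_stats <- lapply(clinical[clinical_ordinal], function(x) {
    stats::median(stage_to_ordinal(x), na.rm = TRUE)
  })
  structure(list(cont = cont_stats, ord_median = ord_stats,
                 missing_indicators = missing_indicators),
            class = "clinical_encoder")
}

#' Encode a clinical table as a numeric matrix
#'
#' Continuous features are median-imputed and z-scored with training
#' statistics; staging variables are collapsed to ordinal main stages
#' (T1a -> T1 etc.), integer-coded, median-imputed with a per-variable
#' missing-indicator column; categoricals are one-hot encoded against a
#' reference level, with an explicit missing level where the cohort schema
#' reports missing samples. Unknown categorical levels at apply time map to
#' the missing level (or the reference, if the variable has none) and are
#' logged.
#'
#' @param clinical clinical table to encode.
#' @param encoder a `clinical_encoder` fitted on training patients.
#' @return numeric matrix, one row per patient.
#' @export
encode_clinical <- function(clinical, encoder) {
  stopifnot(inherits(encoder, "clinical_encoder"))
  n <- nrow(clinical)
  cols <- list()
  cont <- data.frame(age = clinical$age,
                     tumor_volume = compute_tumor_volume(clinical),
                     pack_years = clinical$pack_years)
  for (v in clinical_continuous) {
    st <- encoder$cont[[v]]
    x <- ifelse(is.na(cont[[v]]), st$median, cont[[v]])
    sc <- if (st$scale > 1e-12) st$scale else 1
    cols[[v]] <- (x - st$center) / sc
  }
  for (v in clinical_ordinal) {
    o <- stage_to_ordinal(clinical[[v]])
    miss <- as.numeric(is.na(o))
    o[is.na(o)] <- encoder$ord_median[[v]]
    cols[[v]] <- o
    if (encoder$missing_indicators) cols[[paste0(v, "_missing")]] <- miss
  }
  for (v in names(clinical_categorical)) {
    sch <- clinical_categorical[[v]]
    x <- as.character(clinical[[v]])
    known <- c(sch$ref, sch$levels)
    unknown <- !is.na(x) & !(x %in% known)
    if (any(unknown)) {
      omicsurv_log(sum(unknown), " unknown level(s) in '", v,
                   "' mapped to the missing level", verbose = TRUE)
      x[unknown] <- NA
    }
    for (lv in sch$levels) {
      cols[[paste0(v, "_", make.names(lv))]] <- as.numeric(!is.na(x) & x == lv)
    }
    if (sch$missing_level && encoder$missing_indicators) {
      cols[[paste0(v, "_missing")]] <- as.numeric(is.na(x))
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(clinical)
  out
}
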