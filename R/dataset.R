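#' Multimodal omics dataset container
#'
#' Bundles aligned per-modality matrices, raw counts for expression
#' modalities, a clinical table, per-patient survival outcomes and a cohort
#' label into a single validated object. All components index the same
#' patients in the same order; feature ids are unique within a modality.
#'
#' @param modalities named list of numeric matrices (patients x features) on
#'   the analysis scale: log-normalized expression for `mrna`/`mirna`/
#'   `lncrna`, beta values in (0,1) for `methylation`. Rows must carry
#'   patient ids, columns feature ids.
#' @param clinical data.frame of clinical covariates, one row per patient.
#' @param survival data.frame with numeric column `time_days` (> 0, days)
#'   and integer/logical column `event` (1 = death observed, 0 = censored).
#' @param cohort character/factor of per-patient cohort labels in
#'   `c("A", "B")` (stand-ins for the two carcinoma cohorts).
#' @param counts optional named list of raw count matrices for expression
#'   modalities, aligned like `modalities`; needed for differential
#'   expression.
#' @param probe_annotation optional data.frame describing methylation probes
#'   (see [generate_probe_annotation()]).
#' @return An object of class `multiomics_dataset`.
#' @export
multiomics_dataset <- function(modalities, clinical, survival, cohort,
                               counts = NULL, probe_annotation = NULL) {
  if (!is.list(modalities) || is.null(names(modalities)) || any(names(modalities) == "")) {
    stopf("`modalities` must be a named list of matrices")
  }
  pid <- rownames(modalities[[1]])
  if (is.null(pid)) stopf("modality matrices must carry patient ids as rownames")
  ds <- structure(
    list(modalities = modalities, clinical = clinical, survival = survival,
         cohort = as.character(cohort), counts = counts,
         probe_annotation = probe_annotation, patient_ids = pid),
    class = "multiomics_dataset")
  validate_dataset(ds)
  ds
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf("multiomics_dataset: %d patients (%d events, %d censored)\n",
              length(x$patient_ids), sum(x$survival$event == 1),
              sum(x$survival$event == 0)))
  for (m in names(x$modalities)) {
    cat(sprintf("  %-12s %6d features%s\n", m, ncol(x$modalities[[m]]),
                if (!is.null(x$counts[[m]])) " (+ raw counts)" else ""))
  }
  cat(sprintf("  %-12s %6d columns\n", "clinical", ncol(x$clinical)))
  cat(sprintf("  cohorts: %s\n",
              paste(sprintf("%s=%d", names(table(x$cohort)), table(x$cohort)),
                    collapse = ", ")))
  invisible(x)
}

#' Number of patients in a dataset
#' @param dataset a `multiomics_dataset`.
#' @return integer patient count.
#' @export
n_patients <- function(dataset) length(dataset$patient_ids)

# Alignment invariant: every component indexes the same patients in the same
# order, and feature ids are unique within each modality.
validate_dataset <- function(ds) {
  pid <- ds$patient_ids
  for (m in names(ds$modalities)) {
    mat <- ds$modalities[[m]]
    if (!identical(rownames(mat), pid)) {
      stopf("modality '%s' patient ids are misaligned", m)
    }
    fid <- colnames(mat)
    if (is.null(fid) || anyDuplicated(fid)) {
      stopf("modality '%s' must have unique feature ids", m)
    }
  }
  for (m in names(ds$counts %||% list())) {
    if (!identical(rownames(ds$counts[[m]]), pid)) {
      stopf("counts for '%s' are misaligned", m)
    }
  }
  if (nrow(ds$clinical) != length(pid)) stopf("clinical table is misaligned")
  if (nrow(ds$survival) != length(pid)) stopf("survival table is misaligned")
  if (!all(c("time_days", "event") %in% names(ds$survival))) {
    stopf("survival must have columns time_days, event")
  }
  if (any(ds$survival$time_days <= 0)) stopf("survival times must be positive")
  if (length(ds$cohort) != length(pid)) stopf("cohort labels are misaligned")
  invisible(TRUE)
}

#' Subset a dataset to a set of patients
#'
#' Applies one patient selection simultaneously to every component, so the
#' alignment invariant is preserved by construction.
#'
#' @param dataset a `multiomics_dataset`.
#' @param idx integer or logical patient index, or character patient ids.
#' @return a `multiomics_dataset` with the selected patients.
#' @export
subset_patients <- function(dataset, idx) {
  if (is.character(idx)) idx <- match(idx, dataset$patient_ids)
  if (is.logical(idx)) idx <- which(idx)
  if (length(idx) == 0) stopf("patient subset is empty")
  mods <- lapply(dataset$modalities, function(m) m[idx, , drop = FALSE])
  cnts <- if (!is.null(dataset$counts)) {
    lapply(dataset$counts, function(m) m[idx, , drop = FALSE])
  }
  multiomics_dataset(
    modalities = mods,
    clinical = dataset$clinical[idx, , drop = FALSE],
    survival = dataset$survival[idx, , drop = FALSE],
    cohort = dataset$cohort[idx],
    counts = cnts,
    probe_annotation = dataset$probe_annotation)
}

#' Subset modality feature columns
#'
#' @param dataset a `multiomics_dataset`.
#' @param modality modality name.
#' @param features character feature ids to retain (order respected).
#' @return the dataset with the modality (and its counts, if present)
#'   restricted to `features`.
#' @export
subset_features <- function(dataset, modality, features) {
  if (!modality %in% names(dataset$modalities)) stopf("unknown modality '%s'", modality)
  if (length(features) == 0) stopf("empty-modality error: no features left in '%s'", modality)
  dataset$modalities[[modality]] <-
    dataset$modalities[[modality]][, features, drop = FALSE]
  if (!is.null(dataset$counts[[modality]])) {
    keep <- intersect(features, colnames(dataset$counts[[modality]]))
    dataset$counts[[modality]] <- dataset$counts[[modality]][, keep, drop = FALSE]
  }
  dataset
}
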