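#' Simulation configuration for the synthetic multi-omics generator
#'
#' Describes a multimodal cohort with a low-dimensional latent structure:
#' patients carry `n_latent` Gaussian latent factors, the first
#' `n_survival_latents` of which drive the hazard; each modality's
#' informative features load on the latent subsets in `signal_allocation`.
#' Two (by default) planted subtypes differ both in the survival-latent
#' means (`subtype_latent_gap`) and by a direct mean shift on informative
#' features (`subtype_shift`, log2 units for count modalities, logit units
#' for methylation), so subtype membership is visible to clustering and to
#' differential expression/methylation.
#'
#' Defaults emulate the real cohort the pipeline targets: 732 NSCLC
#' patients, ~61% censored, two cohorts, with per-modality feature counts
#' scaled to desk size.
#'
#' @param n_patients number of patients.
#' @param cohort_fraction fraction of patients in cohort A.
#' @param features_per_modality named integer vector of feature counts for
#'   `mrna`, `mirna`, `lncrna`, `methylation`.
#' @param n_latent number of latent factors per patient.
#' @param n_survival_latents how many leading latents carry hazard signal.
#' @param signal_allocation named list: modality -> integer latent indices
#'   its informative features load on.
#' @param frac_informative fraction of each modality's features loading on
#'   any latent.
#' @param effect_size log-hazard coefficient per survival latent.
#' @param baseline_hazard_scale,baseline_hazard_shape Weibull baseline
#'   parameters (days).
#' @param censoring_rate target fraction of patients censored.
#' @param missing_rate per-entry missingness probability (background).
#' @param elevated_missing_frac,elevated_missing_rate fraction of features
#'   given an elevated missingness rate, and that rate, so the 20%
#'   missingness filter has true positives.
#' @param n_subtypes planted cluster count.
#' @param subtype_shift mean shift applied to informative features per
#'   subtype (log2 / logit scale).
#' @param subtype_latent_gap separation of survival-latent means between
#'   subtypes (per latent, latent-SD units).
#' @param dispersion negative-binomial dispersion of raw counts
#'   (variance = mu + dispersion * mu^2).
#' @param frac_probes_in_scope fraction of methylation probes in a CpG
#'   island and within 1500 bp upstream of the TSS.
#' @param seed RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 732L,
                       cohort_fraction = 0.55,
                       features_per_modality = c(mrna = 2000L, mirna = 300L,
                                                 lncrna = 800L, methylation = 3000L),
                       n_latent = 10L,
                       n_survival_latents = 4L,
                       signal_allocation = list(mrna = c(1L, 2L, 5L, 6L),
                                                methylation = c(2L, 3L, 7L, 8L),
                                                lncrna = c(1L, 3L, 9L),
                                                mirna = c(4L, 10L)),
                       frac_informative = 0.10,
                       effect_size = 1.0,
                       baseline_hazard_scale = 1500,
                       baseline_hazard_shape = 1.2,
                       censoring_rate = 0.613,
                       missing_rate = 0.02,
                       elevated_missing_frac = 0.04,
                       elevated_missing_rate = 0.35,
                       n_subtypes = 2L,
                       subtype_shift = 1.5,
                       subtype_latent_gap = 1.5,
                       dispersion = 0.2,
                       frac_probes_in_scope = 0.35,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              cohort_fraction = cohort_fraction,
              features_per_modality = features_per_modality,
              n_latent = as.integer(n_latent),
              n_survival_latents = as.integer(n_survival_latents),
              signal_allocation = signal_allocation,
              frac_informative = frac_informative,
              effect_size = effect_size,
              baseline_hazard_scale = baseline_hazard_scale,
              baseline_hazard_shape = baseline_hazard_shape,
              censoring_rate = censoring_rate,
              missing_rate = missing_rate,
              elevated_missing_frac = elevated_missing_frac,
              elevated_missing_rate = elevated_missing_rate,
              n_subtypes = as.integer(n_subtypes),
              subtype_shift = subtype_shift,
              subtype_latent_gap = subtype_latent_gap,
              dispersion = dispersion,
              frac_probes_in_scope = frac_probes_in_scope,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_patients)) stopf("configuration error: n_patients must be a positive integer")
  if (any(cfg$features_per_modality < 1)) stopf("configuration error: zero features in a modality")
  for (f in c("cohort_fraction", "frac_informative", "censoring_rate",
              "missing_rate", "elevated_missing_frac", "elevated_missing_rate",
              "frac_probes_in_scope")) {
    if (!is_fraction(cfg[[f]])) stopf("configuration error: %s must lie in [0,1]", f)
  }
  if (cfg$n_survival_latents > cfg$n_latent) {
    stopf("configuration error: n_survival_latents exceeds n_latent")
  }
  for (m in names(cfg$signal_allocation)) {
    if (!m %in% names(cfg$features_per_modality)) {
      stopf("configuration error: signal_allocation names modality '%s' absent from features_per_modality", m)
    }
    if (any(cfg$signal_allocation[[m]] > cfg$n_latent)) {
      stopf("configuration error: signal_allocation for '%s' references latent > n_latent", m)
    }
  }
  if (cfg$censoring_rate %in% c(0, 1)) {
    omicsurv_log("censoring_rate is ", cfg$censoring_rate,
                 " (degenerate but allowed)", verbose = TRUE)
  }
  invisible(TRUE)
}

# Subtype center coding: equally spaced, zero-mean offsets. K = 2 -> c(-.5, .5).
subtype_centers <- function(k) seq_len(k) - (k + 1) / 2

#' Generate a synthetic multimodal dataset with ground truth
#'
#' Patients receive latent factors `Z` (survival latents shifted per planted
#' subtype), a clinical table mirroring the 11-feature schema, and per
#' modality: negative-binomial raw counts plus log-CPM normalized values
#' (expression), or logit-normal beta values (methylation). Survival times
#' follow a Weibull proportional-hazards model with linear predictor
#' `effect_size * rowSums(Z_survival) + clinical term`; independent
#' exponential censoring is tuned numerically so the realized censored
#' fraction approximates `censoring_rate`. Identical `(config, seed)` pairs
#' give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return list with elements `dataset` (a [multiomics_dataset()]) and
#'   `truth` (latent matrix, informative feature ids per modality, net
#'   planted between-subtype effect per feature, subtype labels, true
#'   linear predictor).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  n <- cfg$n_patients
  pid <- sprintf("PT%04d", seq_len(n))

  subtype <- sample(rep_len(seq_len(cfg$n_subtypes), n))
  centers <- subtype_centers(cfg$n_subtypes)

  Z <- matrix(rnorm(n * cfg$n_latent), n, cfg$n_latent)
  if (cfg$n_survival_latents > 0) {
    off <- cfg$subtype_latent_gap * centers[subtype]
    Z[, seq_len(cfg$n_survival_latents)] <-
      Z[, seq_len(cfg$n_survival_latents)] + off
  }

  cohort <- ifelse(runif(n) < cfg$cohort_fraction, "A", "B")
  clinical <- simulate_clinical(n, cohort)

  # hazard linear predictor: survival latents plus a clinical covariate term
  z_age <- (clinical$age - 66.1) / 9.5
  z_age[is.na(z_age)] <- 0
  stage_ord <- stage_to_ordinal(clinical$pathological_stage)
  stage_ord[is.na(stage_ord)] <- mean(stage_ord, na.rm = TRUE)
  lp_surv <- if (cfg$n_survival_latents > 0) {
    cfg$effect_size * rowSums(Z[, seq_len(cfg$n_survival_latents), drop = FALSE])
  } else rep(0, n)
  lp <- lp_surv + 0.3 * z_age + 0.4 * (stage_ord - mean(stage_ord))

  surv <- simulate_survival(lp, cfg)

  mods <- list()
  cnts <- list()
  informative <- list()
  planted_effects <- list()
  # between-subtype contrast (last minus first center); 0 when K = 1
  cd <- if (cfg$n_subtypes > 1) centers[2] - centers[1] else 0
  for (m in names(cfg$features_per_modality)) {
    p <- cfg$features_per_modality[[m]]
    fid <- if (m == "methylation") sprintf("cg%07d", seq_len(p)) else sprintf("%s_%05d", m, seq_len(p))
    n_inf <- max(1L, round(cfg$frac_informative * p))
    inf_idx <- sort(sample.int(p, n_inf))
    informative[[m]] <- fid[inf_idx]

    latents <- cfg$signal_allocation[[m]] %||% integer(0)
    signal <- matrix(0, n, p)
    if (length(latents) > 0 && n_inf > 0) {
      W <- matrix(0, cfg$n_latent, n_inf)
      W[latents, ] <- matrix(sample(c(-1, 1), length(latents) * n_inf, replace = TRUE) *
                               runif(length(latents) * n_inf, 0.5, 1),
                             length(latents), n_inf)
      signal[, inf_idx] <- Z %*% W
    }
    shift_dir <- numeric(p)
    shift_dir[inf_idx] <- sample(c(-1, 1), n_inf, replace = TRUE)
    shift <- outer(centers[subtype], shift_dir) * cfg$subtype_shift

    # net planted between-subtype mean difference per feature (log2 units
    # for counts, logit units for methylation): the direct shift plus the
    # subtype offset propagated through survival-latent loadings -- the
    # two can reinforce or cancel, so this, not membership in
    # informative_features, defines the planted DE truth
    delta <- cd * shift_dir * cfg$subtype_shift
    if (length(latents) > 0 && n_inf > 0 && cfg$n_survival_latents > 0) {
      surv_rows <- seq_len(cfg$n_survival_latents)
      delta[inf_idx] <- delta[inf_idx] +
        cd * cfg$subtype_latent_gap * colSums(W[surv_rows, , drop = FALSE])
    }
    names(delta) <- fid
    planted_effects[[m]] <- delta

    if (m == "methylation") {
      mu0 <- rnorm(p, 0, 2)  # baseline M-value (log2-odds) per probe
      g <- sweep(signal + shift + matrix(rnorm(n * p, 0, 0.5), n, p), 2, mu0, "+")
      beta <- 1 / (1 + 2^(-g))
      dimnames(beta) <- list(pid, fid)
      mods[[m]] <- beta
    } else {
      mu0 <- runif(p, 2, 9)  # baseline log2 mean expression
      libsize <- exp(rnorm(n, 0, 0.2))
      log2mu <- sweep(signal + shift, 2, mu0, "+")
      mu <- libsize * 2^log2mu
      counts <- matrix(rnbinom(n * p, mu = mu, size = 1 / cfg$dispersion), n, p)
      dimnames(counts) <- list(pid, fid)
      norm <- log2(1e6 * counts / rowSums(counts) + 1)
      mods[[m]] <- norm
      cnts[[m]] <- counts
    }
  }

  ann <- if ("methylation" %in% names(cfg$features_per_modality)) {
    generate_probe_annotation(config = cfg,
                              probe_ids = colnames(mods$methylation),
                              seed = NULL)
  }

  ds <- multiomics_dataset(modalities = mods, clinical = clinical,
                           survival = surv, cohort = cohort,
                           counts = if (length(cnts)) cnts else NULL,
                           probe_annotation = ann)
  ds <- inject_missingness(ds, cfg$missing_rate, seed = NULL,
                           elevated_frac = cfg$elevated_missing_frac,
                           elevated_rate = cfg$elevated_missing_rate)
  truth <- list(latent_matrix = Z,
                informative_features = informative,
                planted_effects = planted_effects,
                subtype_labels = subtype,
                true_linear_predictor = lp)
  list(dataset = ds, truth = truth)
}

# Weibull PH sampling: S(t|lp) = exp(-(t/scale)^shape * exp(lp)), so
# T = scale * (E / exp(lp))^(1/shape) with E ~ Exp(1). Censoring C ~ Exp(r)
# with r solved so that mean_i P(C < T_i | T_i) hits the target fraction.
simulate_survival <- function(lp, cfg) {
  n <- length(lp)
  E <- rexp(n)
  T <- cfg$baseline_hazard_scale * (E / exp(lp))^(1 / cfg$baseline_hazard_shape)
  if (cfg$censoring_rate <= 0) {
    time <- pmin(T, 11000)
    return(data.frame(time_days = time, event = as.integer(T <= 11000)))
  }
  if (cfg$censoring_rate >= 1) {
    C <- T * runif(n)  # censor strictly before every event
    return(data.frame(time_days = pmax(C, .Machine$double.eps), event = 0L))
  }
  f <- function(logr) mean(1 - exp(-exp(logr) * T)) - cfg$censoring_rate
  logr <- stats::uniroot(f, c(-30, 10))$root
  C <- rexp(n, exp(logr))
  time <- pmin(T, C, 11000)
  event <- as.integer(T <= C & T <= 11000)
  data.frame(time_days = pmax(time, .Machine$double.eps), event = event)
}

# Clinical table mirroring the 11-feature schema (age, sex, tumor dimensions
# -> volume, diagnosis, prior/synchronous malignancy, staging, pack-years),
# with realistic missingness rates scaled from the published cohort table.
simulate_clinical <- function(n, cohort) {
  miss <- function(x, p) {x[runif(n) < p] <- NA; x}
  truncnorm <- function(n, mean, sd, lo, hi) pmin(pmax(rnorm(n, mean, sd), lo), hi)
  d1 <- truncnorm(n, 1.0, 0.4, 0.2, 4)
  d2 <- truncnorm(n, 0.9, 0.35, 0.2, 4)
  d3 <- truncnorm(n, 0.6, 0.3, 0.1, 3)
  stage_lv <- c("Stage 1", "Stage 1A", "Stage 1B", "Stage 2", "Stage 2A",
                "Stage 2B", "Stage 3", "Stage 3A", "Stage 3B", "Stage 4")
  stage_pr <- c(.04, .22, .18, .03, .12, .10, .02, .14, .08, .07)
  data.frame(
    age = miss(truncnorm(n, 66.1, 9.5, 30, 95), 14 / 732),
    sex = sample(c("Male", "Female"), n, replace = TRUE, prob = c(.6, .4)),
    tumor_dim1 = miss(d1, 220 / 732),
    tumor_dim2 = miss(d2, 220 / 732),
    tumor_dim3 = miss(d3, 220 / 732),
    primary_diagnosis = ifelse(cohort == "A", "Adenocarcinoma", "Squamous cell carcinoma"),
    prior_malignancy = sample(c("Yes", "No"), n, replace = TRUE, prob = c(.15, .85)),
    synchronous_malignancy = miss(sample(c("Yes", "No"), n, replace = TRUE, prob = c(.07, .93)), 54 / 732),
    pathological_stage = miss(sample(stage_lv, n, replace = TRUE, prob = stage_pr), 8 / 732),
    staging_t = miss(sample(c("T1", "T1a", "T1b", "T2", "T2a", "T2b", "T3", "T4"),
                            n, replace = TRUE,
                            prob = c(.05, .12, .13, .08, .25, .12, .15, .10)), 3 / 732),
    staging_n = miss(sample(c("N0", "N1", "N2"), n, replace = TRUE, prob = c(.6, .25, .15)), 12 / 732),
    staging_m = miss(sample(c("M0", "M1", "M1a", "M1b"), n, replace = TRUE,
                            prob = c(.92, .04, .02, .02)), 199 / 732),
    pack_years = miss(truncnorm(n, 46.2, 28.1, 0, 160), 180 / 732),
    stringsAsFactors = FALSE)
}

#' Inject entry-level missingness into a dataset
#'
#' Each expression/methylation entry is independently replaced with `NA`
#' (and the matching raw count set to 0) with probability `missing_rate`.
#' A configurable subset of features receives an elevated rate so the 20%
#' missingness filter has true positives.
#'
#' @param dataset a `multiomics_dataset`.
#' @param missing_rate background per-entry missingness probability.
#' @param seed RNG seed (`NULL` to use the current stream).
#' @param elevated_frac fraction of features per modality given the
#'   elevated rate.
#' @param elevated_rate the elevated per-entry rate.
#' @return the dataset with missingness applied.
#' @export
inject_missingness <- function(dataset, missing_rate, seed = NULL,
                               elevated_frac = 0, elevated_rate = 0) {
  stopifnot(is_fraction(missing_rate))
  with_seed(seed, {
    for (m in names(dataset$modalities)) {
      mat <- dataset$modalities[[m]]
      p <- ncol(mat)
      rate <- rep(missing_rate, p)
      if (elevated_frac > 0) {
        n_elev <- round(elevated_frac * p)
        if (n_elev > 0) rate[sample.int(p, n_elev)] <- elevated_rate
      }
      mask <- sweep(matrix(runif(length(mat)), nrow(mat), p), 2, rate, "<")
      mat[mask] <- NA
      dataset$modalities[[m]] <- mat
      if (!is.null(dataset$counts[[m]])) {
        cc <- dataset$counts[[m]]
        cc[mask] <- 0L
        dataset$counts[[m]] <- cc
      }
    }
    dataset
  })
}

#' Generate a methylation probe annotation table
#'
#' Each probe maps to exactly one gene; several probes share a gene (needed
#' for probe-to-gene M-value averaging). A configurable fraction of probes
#' is inside a CpG island and within 1500 bp upstream of the TSS; the rest
#' are split between non-island, island-but-distant, and downstream probes.
#' Downstream probes carry `upstream = FALSE` and `NA` distance rather than
#' a negative distance.
#'
#' @param config a [sim_config()] (uses `frac_probes_in_scope` and the
#'   methylation feature count).
#' @param probe_ids optional explicit probe ids (defaults to the
#'   configured methylation feature count).
#' @param seed RNG seed (`NULL` to use the current stream).
#' @return data.frame with columns `probe_id`, `gene_id`, `in_cpg_island`,
#'   `upstream`, `distance_upstream_tss`.
#' @export
generate_probe_annotation <- function(config, probe_ids = NULL, seed = NULL) {
  if (is.null(probe_ids)) {
    p <- config$features_per_modality[["methylation"]]
    if (is.null(p)) stopf("configuration error: methylation modality absent")
    probe_ids <- sprintf("cg%07d", seq_len(p))
  }
  p <- length(probe_ids)
  frac <- config$frac_probes_in_scope
  with_seed(seed, {
    n_genes <- max(1L, round(p / 3))
    gene_id <- sprintf("GENE%05d", sample.int(n_genes, p, replace = TRUE))
    n_in <- round(frac * p)
    in_scope <- seq_len(p) %in% sample.int(p, n_in)
    in_island <- logical(p)
    upstream <- logical(p)
    dist <- rep(NA_integer_, p)
    in_island[in_scope] <- TRUE
    upstream[in_scope] <- TRUE
    dist[in_scope] <- sample(0:1500, n_in, replace = TRUE)
    out <- which(!in_scope)
    if (length(out) > 0) {
      kind <- sample(1:3, length(out), replace = TRUE)
      # 1: not in island (any distance); 2: in island but > 1500 upstream;
      # 3: downstream (sentinel NA distance)
      k1 <- out[kind == 1]; k2 <- out[kind == 2]; k3 <- out[kind == 3]
      in_island[k2] <- TRUE
      upstream[c(k1, k2)] <- TRUE
      dist[k1] <- sample(0:5000, length(k1), replace = TRUE)
      dist[k2] <- sample(1501:5000, length(k2), replace = TRUE)
      in_island[k3] <- sample(c(TRUE, FALSE), length(k3), replace = TRUE)
    }
    data.frame(probe_id = probe_ids, gene_id = gene_id,
               in_cpg_island = in_island, upstream = upstream,
               distance_upstream_tss = dist, stringsAsFactors = FALSE)
  })
}

#' Write a dataset to a directory of delimited text files
#'
#' One TSV per modality (rows = features, columns = patient ids; raw counts
#' in `<modality>_counts.tsv`), a `patients.tsv` (clinical + survival +
#' cohort), a `probe_annotation.tsv`, and `ground_truth.json` when truth is
#' supplied.
#'
#' @param dataset a `multiomics_dataset`.
#' @param dir output directory (created if needed).
#' @param truth optional ground-truth list from [generate_dataset()].
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                             quote = FALSE, row.names = TRUE,
                                             col.names = NA)
  for (m in names(dataset$modalities)) {
    wtsv(t(dataset$modalities[[m]]), paste0(m, ".tsv"))
    if (!is.null(dataset$counts[[m]])) {
      wtsv(t(dataset$counts[[m]]), paste0(m, "_counts.tsv"))
    }
  }
  pat <- cbind(dataset$clinical,
               cohort = dataset$cohort,
               dataset$survival)
  rownames(pat) <- dataset$patient_ids
  wtsv(pat, "patients.tsv")
  if (!is.null(dataset$probe_annotation)) {
    utils::write.table(dataset$probe_annotation, file.path(dir, "probe_annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(informative_features = truth$informative_features,
           subtype_labels = truth$subtype_labels,
           true_linear_predictor = truth$true_linear_predictor,
           latent_matrix = truth$latent_matrix),
      file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing the TSV files.
#' @return a `multiomics_dataset`.
#' @export
read_dataset <- function(dir) {
  rtsv <- function(f) as.matrix(utils::read.table(file.path(dir, f), sep = "\t",
                                                  header = TRUE, row.names = 1,
                                                  check.names = FALSE))
  files <- list.files(dir)
  mod_names <- sub("\\.tsv$", "", grep("^(mrna|mirna|lncrna|methylation)\\.tsv$", files, value = TRUE))
  mods <- lapply(mod_names, function(m) t(rtsv(paste0(m, ".tsv"))))
  names(mods) <- mod_names
  cnt_names <- sub("_counts\\.tsv$", "", grep("_counts\\.tsv$", files, value = TRUE))
  cnts <- if (length(cnt_names)) {
    stats::setNames(lapply(cnt_names, function(m) t(rtsv(paste0(m, "_counts.tsv")))), cnt_names)
  }
  pat <- utils::read.table(file.path(dir, "patients.tsv"), sep = "\t", header = TRUE,
                           row.names = 1, check.names = FALSE, stringsAsFactors = FALSE)
  ann <- if (file.exists(file.path(dir, "probe_annotation.tsv"))) {
    utils::read.table(file.path(dir, "probe_annotation.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
  }
  clin_cols <- setdiff(names(pat), c("cohort", "time_days", "event"))
  multiomics_dataset(modalities = mods,
                     clinical = pat[, clin_cols, drop = FALSE],
                     survival = data.frame(time_days = pat$time_days, event = pat$event),
                     cohort = pat$cohort, counts = cnts, probe_annotation = ann)
}
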