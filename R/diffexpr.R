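# Differential expression between survival subtypes: a specified
# negative-binomial Wald test on raw counts with median-of-ratios size
# factors and method-of-moments dispersion, Benjamini-Hochberg adjustment;
# and M-value ANOVA for differential methylation. This is deliberately a
# transparent NB-Wald procedure, not a re-implementation of shrinkage-based
# DE estimators.

#' Median-of-ratios size factors
#'
#' Per-sample size factor: the median, over genes with positive geometric
#' mean, of the ratio of the sample's count to the gene's geometric mean.
#'
#' When zero inflation leaves no gene with all-positive counts (the usual
#' case at realistic cohort sizes), the "poscounts" variant is used: the
#' per-gene geometric mean is taken over positive counts only (with the
#' zero count still in the denominator), and each sample's median ratio is
#' computed over its positive counts.
#'
#' @param counts patients x genes raw count matrix.
#' @return numeric size factor per patient.
#' @export
size_factors_median_ratios <- function(counts) {
  cg <- t(counts)                   # genes x samples
  lg <- log(cg)
  gmean <- rowMeans(lg)             # -Inf for genes with any zero
  use <- is.finite(gmean)
  if (any(use)) {
    sf <- apply(exp(lg[use, , drop = FALSE] - gmean[use]), 2, stats::median)
  } else {
    lp <- lg
    lp[!is.finite(lp)] <- 0
    gmean <- exp(rowSums(lp) / ncol(cg))
    use <- gmean > 0 & rowSums(cg > 0) > 0
    if (!any(use)) stopf("cannot estimate size factors: no usable genes")
    ratio <- cg[use, , drop = FALSE] / gmean[use]
    sf <- apply(ratio, 2, function(r) stats::median(r[r > 0]))
  }
  if (any(!is.finite(sf) | sf <= 0)) stopf("non-positive size factor estimated")
  sf
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Own implementation of the BH step-up procedure: adjusted p-values are
#' `min_{j >= i} p_(j) * m / j`, capped at 1, mapped back to input order.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values (monotone in raw-p rank, never below raw p).
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[ord] * m / seq(m, 1)))
  adj[order(ord)]
}

#' Negative-binomial Wald differential expression
#'
#' Normalizes counts with median-of-ratios size factors, estimates a
#' per-gene dispersion by pooled method of moments
#' (`var = mu + dispersion * mu^2`, floored at 1e-8), and Wald-tests the
#' group log2 fold change via a delta-method standard error. P-values are
#' BH-adjusted within the modality; a transcript is significant when the
#' adjusted p-value is below `alpha` and the absolute fold change exceeds
#' `fc_threshold`. Genes with all-zero counts are excluded and reported.
#'
#' @param counts patients x genes raw (unnormalized) count matrix.
#' @param labels two-group per-patient labels; log2FC is group 1 minus
#'   group 2 in the sorted label order.
#' @param alpha FDR threshold.
#' @param fc_threshold fold-change threshold (absolute, linear scale).
#' @param pseudocount added to normalized group means before the ratio.
#' @return a `differential_result` data.frame with columns `id`,
#'   `log2fc`, `se`, `p`, `adj_p`, `significant`; attribute
#'   `excluded` lists all-zero genes.
#' @export
differential_expression <- function(counts, labels, alpha = 0.05,
                                    fc_threshold = 1.5, pseudocount = 0.5) {
  groups <- sort(unique(labels))
  if (length(groups) != 2) stopf("differential expression requires exactly 2 groups")
  i1 <- labels == groups[1]
  i2 <- labels == groups[2]
  if (sum(i1) < 2 || sum(i2) < 2) stopf("each group needs at least 2 samples")
  excluded <- colnames(counts)[colSums(counts) == 0]
  keep <- colSums(counts) > 0
  counts <- counts[, keep, drop = FALSE]
  sf <- size_factors_median_ratios(counts)
  q <- counts / sf

  gstats <- function(idx) {
    n <- sum(idx)
    mu <- colMeans(q[idx, , drop = FALSE])
    v <- apply(q[idx, , drop = FALSE], 2, stats::var)
    list(n = n, mu = mu, v = v)
  }
  s1 <- gstats(i1)
  s2 <- gstats(i2)
  # pooled method-of-moments dispersion: var = mu + a * mu^2 within groups
  num <- (s1$n - 1) * (s1$v - s1$mu) + (s2$n - 1) * (s2$v - s2$mu)
  den <- (s1$n - 1) * s1$mu^2 + (s2$n - 1) * s2$mu^2
  disp <- pmax(num / pmax(den, 1e-12), 1e-8)

  m1 <- s1$mu + pseudocount
  m2 <- s2$mu + pseudocount
  log2fc <- log2(m1 / m2)
  # delta method on log of the group mean of NB variables
  vlog1 <- (s1$mu + disp * s1$mu^2) / (s1$n * m1^2)
  vlog2 <- (s2$mu + disp * s2$mu^2) / (s2$n * m2^2)
  se <- sqrt(vlog1 + vlog2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  # Wald statistic referenced to a t distribution (df = n1 + n2 - 2): the
  # SE carries estimated MoM dispersion, and a normal reference is
  # anti-conservative in the far tail at realistic group sizes
  p <- 2 * stats::pt(-abs(z), df = s1$n + s2$n - 2)
  adj <- bh_adjust(p)
  out <- data.frame(id = colnames(counts), log2fc = log2fc, se = se,
                    p = p, adj_p = adj,
                    significant = adj < alpha & abs(log2fc) > log2(fc_threshold),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  class(out) <- c("differential_result", class(out))
  out
}

# Vectorized one-way ANOVA across matrix columns.
anova_oneway_matrix <- function(Y, labels) {
  groups <- sort(unique(labels))
  K <- length(groups)
  n <- nrow(Y)
  grand <- colMeans(Y)
  ssb <- 0
  ssw <- 0
  for (g in groups) {
    idx <- labels == g
    mg <- colMeans(Y[idx, , drop = FALSE])
    ssb <- ssb + sum(idx) * (mg - grand)^2
    ssw <- ssw + colSums(sweep(Y[idx, , drop = FALSE], 2, mg)^2)
  }
  Fstat <- (ssb / (K - 1)) / (ssw / (n - K))
  p <- stats::pf(Fstat, K - 1, n - K, lower.tail = FALSE)
  list(F = Fstat, p = p, df1 = K - 1, df2 = n - K)
}

#' Differential methylation by per-gene M-value ANOVA
#'
#' Transforms betas to M-values, averages M across each gene's probes per
#' patient, and applies a classical equal-variance one-way ANOVA per gene.
#' Significance is at raw `p < alpha` (no multiplicity correction, noted in
#' the result metadata); the reported effect is the mean M difference
#' (group 1 minus group 2).
#'
#' @param beta patients x probes beta-value matrix.
#' @param labels per-patient group labels (2 or more groups; the mean
#'   difference is reported for the first two).
#' @param annotation probe annotation with `probe_id` and `gene_id`.
#' @param alpha raw p-value threshold.
#' @return data.frame with columns `gene`, `n_probes`, `mean_m_diff`,
#'   `F`, `p`, `significant`; attribute `multiplicity` = "none".
#' @export
differential_methylation <- function(beta, labels, annotation, alpha = 0.05) {
  probes <- colnames(beta)
  ann <- annotation[match(probes, annotation$probe_id), ]
  if (anyNA(ann$gene_id)) stopf("annotation does not cover all probes")
  M <- beta_to_m(beta)
  # per-gene mean M across probes, per patient (averaging identity for
  # single-probe genes); missing probe values excluded pairwise, any
  # patient left without a value gets the gene median
  gidx <- split(seq_along(probes), ann$gene_id)
  gm <- vapply(gidx, function(ix) rowMeans(M[, ix, drop = FALSE], na.rm = TRUE),
               numeric(nrow(M)))
  if (anyNA(gm) || any(!is.finite(gm))) {
    gm[!is.finite(gm)] <- NA
    med <- apply(gm, 2, stats::median, na.rm = TRUE)
    nas <- which(is.na(gm), arr.ind = TRUE)
    if (nrow(nas)) gm[nas] <- med[nas[, 2]]
  }
  res <- anova_oneway_matrix(gm, labels)
  groups <- sort(unique(labels))
  d <- colMeans(gm[labels == groups[1], , drop = FALSE]) -
    colMeans(gm[labels == groups[2], , drop = FALSE])
  out <- data.frame(gene = colnames(gm),
                    n_probes = lengths(gidx)[colnames(gm)],
                    mean_m_diff = d, F = res$F, p = res$p,
                    significant = res$p < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "multiplicity") <- "none"
  out
}

#' Run the full differential arm for a subtype result
#'
#' Differential expression on each count modality and differential
#' methylation on the beta matrix, using the subtype labels.
#'
#' @param dataset a `multiomics_dataset` with raw counts.
#' @param labels per-patient subtype labels aligned with `dataset` (e.g.
#'   from [discover_subtypes()]).
#' @param alpha FDR / p-value threshold.
#' @param fc_threshold DE fold-change threshold.
#' @return named list: one `differential_result` per count modality, plus
#'   `methylation` when present.
#' @export
differential_analysis <- function(dataset, labels, alpha = 0.05, fc_threshold = 1.5) {
  out <- list()
  for (m in names(dataset$counts %||% list())) {
    out[[m]] <- differential_expression(dataset$counts[[m]], labels,
                                        alpha = alpha, fc_threshold = fc_threshold)
  }
  if ("methylation" %in% names(dataset$modalities) && !is.null(dataset$probe_annotation)) {
    out$methylation <- differential_methylation(dataset$modalities$methylation,
                                                labels, dataset$probe_annotation,
                                                alpha = alpha)
  }
  out
}
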