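# Biomarker-discovery arm: k-means survival subtypes on the elastic-net-
# retained multimodal feature columns, silhouette-based K selection, and
# Kaplan-Meier / log-rank comparison of the resulting groups.

#' Survival-associated feature columns of an elastic-net fit
#'
#' @param fit a `cox_fit` from one designated training run.
#' @return character ids of the nonzero-coefficient columns.
#' @export
survival_feature_set <- function(fit) {
  ids <- names(fit$coefficients)[fit$coefficients != 0]
  if (length(ids) == 0) {
    stopf("all coefficients are zero at lambda = %.4g; refit with a smaller lambda", fit$lambda)
  }
  ids
}

squared_dists <- function(X, C) {
  # n x k matrix of squared Euclidean distances between rows of X and C
  outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- squared_dists(X, centers[1, , drop = FALSE])[, 1]
  for (j in 2:k) {
    probs <- pmax(d2, 0)
    if (sum(probs) <= 0) probs <- rep(1, n)
    centers[j, ] <- X[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, squared_dists(X, centers[j, , drop = FALSE])[, 1])
  }
  centers
}

#' K-means clustering (Lloyd's algorithm, k-means++ starts)
#'
#' Best of `n_restarts` k-means++ initializations by within-cluster sum of
#' squares; deterministic per seed. A restart producing an empty cluster is
#' re-seeded. Output labels are relabelled by descending cluster size (ties
#' by ascending centroid norm) so label ids are reproducible.
#'
#' @param X numeric matrix (patients x features).
#' @param k number of clusters (>= 2, < number of rows).
#' @param seed RNG seed.
#' @param n_restarts number of independent initializations.
#' @param max_iter Lloyd iteration cap per restart.
#' @return list with `labels`, `centers`, `wss`.
#' @export
kmeans_cluster <- function(X, k, seed = 1L, n_restarts = 25, max_iter = 100) {
  X <- as.matrix(X)
  if (k < 2) stopf("k must be >= 2")
  if (nrow(X) <= k) stopf("need more patients than clusters")
  with_seed(seed, {
    best <- NULL
    r <- 0
    attempts <- 0
    while (r < n_restarts && attempts < 10 * n_restarts) {
      attempts <- attempts + 1
      C <- kmeanspp_init(X, k)
      lab <- NULL
      empty <- FALSE
      for (it in seq_len(max_iter)) {
        d2 <- squared_dists(X, C)
        new_lab <- max.col(-d2, ties.method = "first")
        if (length(unique(new_lab)) < k) {empty <- TRUE; break}
        if (identical(new_lab, lab)) break
        lab <- new_lab
        for (j in seq_len(k)) C[j, ] <- colMeans(X[lab == j, , drop = FALSE])
      }
      if (empty) next  # re-seed this restart
      r <- r + 1
      wss <- sum((X - C[lab, , drop = FALSE])^2)
      if (is.null(best) || wss < best$wss) best <- list(labels = lab, centers = C, wss = wss)
    }
    if (is.null(best)) stopf("k-means failed to produce %d non-empty clusters", k)
    # canonical labelling: descending size, ties by ascending centroid norm
    size <- tabulate(best$labels, k)
    norm <- sqrt(rowSums(best$centers^2))
    ord <- order(-size, norm)
    relab <- match(seq_len(k), ord)
    best$labels <- relab[best$labels]
    best$centers <- best$centers[ord, , drop = FALSE]
    best
  })
}

#' Mean silhouette width of a clustering
#'
#' `s(i) = (b - a) / max(a, b)` with `a` the mean Euclidean distance to the
#' own cluster and `b` the smallest mean distance to another cluster;
#' singletons score 0.
#'
#' @param X numeric matrix.
#' @param labels integer cluster labels.
#' @return mean silhouette width.
#' @export
silhouette_width <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  ks <- sort(unique(labels))
  D <- as.matrix(stats::dist(X))
  s <- numeric(n)
  sums <- vapply(ks, function(k) rowSums(D[, labels == k, drop = FALSE]), numeric(n))
  counts <- vapply(ks, function(k) sum(labels == k), numeric(1))
  for (i in seq_len(n)) {
    k_i <- match(labels[i], ks)
    if (counts[k_i] <= 1) {s[i] <- 0; next}
    a <- sums[i, k_i] / (counts[k_i] - 1)
    b <- min(sums[i, -k_i] / counts[-k_i])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Choose the cluster count by silhouette profile
#'
#' Runs [kmeans_cluster()] for each K in `k_min:k_max`, scores each
#' clustering by mean silhouette width, and returns the argmax (ties broken
#' toward smaller K). A uniformly low profile (all widths < 0.3) triggers a
#' low-separation warning.
#'
#' @param X numeric matrix.
#' @param k_min,k_max K range (2..10 by default).
#' @param seed RNG seed.
#' @param n_restarts restarts per K.
#' @return list with `k`, `silhouette_by_k` (named numeric) and
#'   `labels` for the chosen K.
#' @export
choose_k_silhouette <- function(X, k_min = 2, k_max = 10, seed = 1L,
                                n_restarts = 25) {
  if (nrow(as.matrix(X)) <= k_max) stopf("need more patients than k_max")
  ks <- k_min:k_max
  labs <- list()
  sil <- stats::setNames(numeric(length(ks)), ks)
  for (i in seq_along(ks)) {
    cl <- kmeans_cluster(X, ks[i], seed = child_seed(seed, ks[i]),
                         n_restarts = n_restarts)
    labs[[i]] <- cl$labels
    sil[i] <- silhouette_width(X, cl$labels)
  }
  best <- which.max(sil)  # which.max takes the first (smallest K) on ties
  if (all(sil < 0.3)) {
    warning("low cluster separation: all mean silhouette widths < 0.3", call. = FALSE)
  }
  list(k = ks[best], silhouette_by_k = sil, labels = labs[[best]])
}

#' Kaplan-Meier product-limit curves per group
#'
#' @param time,event survival data.
#' @param labels per-patient group labels.
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `survival` (one row per distinct event time per group).
#' @export
kaplan_meier <- function(time, event, labels) {
  rows <- lapply(sort(unique(labels)), function(g) {
    t_g <- time[labels == g]
    e_g <- event[labels == g] != 0
    if (length(t_g) == 0) stopf("empty group '%s'", g)
    dt <- sort(unique(t_g[e_g]))
    if (length(dt) == 0) {  # all censored: S(t) = 1 throughout, no steps
      return(data.frame(group = rep(g, 0), time = numeric(0), n_risk = numeric(0),
                        n_event = numeric(0), survival = numeric(0)))
    }
    n_risk <- vapply(dt, function(t) sum(t_g >= t), numeric(1))
    d <- vapply(dt, function(t) sum(t_g == t & e_g), numeric(1))
    data.frame(group = g, time = dt, n_risk = n_risk, n_event = d,
               survival = cumprod(1 - d / n_risk))
  })
  do.call(rbind, rows)
}

#' Log-rank test for survival differences between groups
#'
#' At each distinct event time, observed events per group are compared with
#' their hypergeometric expectation given the risk sets; the summed
#' observed-minus-expected vector is scored against its covariance,
#' yielding a chi-square statistic with (groups - 1) degrees of freedom.
#'
#' @param time,event survival data.
#' @param labels per-patient group labels (2 or more groups).
#' @return list with `chi_square`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, labels) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  G <- length(groups)
  if (G < 2) stopf("need at least 2 groups")
  ev <- event != 0
  if (!any(ev)) stopf("no events")
  dt <- sort(unique(time[ev]))
  OE <- numeric(G)
  V <- matrix(0, G, G)
  for (t in dt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & ev)
    if (n <= 1) next
    n_g <- vapply(groups, function(g) sum(at_risk & labels == g), numeric(1))
    d_g <- vapply(groups, function(g) sum(time == t & ev & labels == g), numeric(1))
    e_g <- d * n_g / n
    OE <- OE + (d_g - e_g)
    fac <- d * (n - d) / (n - 1)
    V <- V + fac * (diag(n_g / n, G) - tcrossprod(n_g / n))
  }
  idx <- seq_len(G - 1)
  Vi <- V[idx, idx, drop = FALSE]
  chi <- if (all(abs(Vi) < 1e-300)) 0 else {
    drop(t(OE[idx]) %*% solve(Vi, OE[idx]))
  }
  list(chi_square = as.numeric(chi), df = G - 1,
       p_value = stats::pchisq(as.numeric(chi), df = G - 1, lower.tail = FALSE))
}

#' Discover survival subtypes from a fitted pipeline run
#'
#' Takes one designated training run (default: the run with the median test
#' C-index), restricts the multimodal feature space (embedding columns +
#' encoded clinical) to the elastic net's nonzero columns, clusters all
#' patients with k-means, selects K by silhouette over 2..10, and compares
#' the resulting groups by Kaplan-Meier and log-rank.
#'
#' @param report a `run_report` produced with `keep_states = TRUE`.
#' @param dataset the dataset the report was produced from.
#' @param run index of the designated run (default median-C-index run).
#' @param k_min,k_max silhouette K range.
#' @param seed RNG seed for clustering.
#' @param n_restarts k-means restarts.
#' @return a `subtype_result`: `labels`, `k`, `silhouette_by_k`,
#'   `logrank`, `km_curves`, `feature_ids`, `run`.
#' @export
discover_subtypes <- function(report, dataset, run = NULL, k_min = 2, k_max = 10,
                              seed = 1L, n_restarts = 25) {
  if (is.null(report$states)) stopf("report lacks fitted states; rerun with keep_states = TRUE")
  if (is.null(run)) {
    ok <- which(!is.na(report$c_indices))
    run <- ok[order(report$c_indices[ok])][ceiling(length(ok) / 2)]
  }
  state <- report$states[[run]]
  if (is.null(state)) stopf("run %d has no fitted state", run)
  dataset <- filter_patients_by_followup(dataset)
  X <- apply_pipeline_state(state, dataset)
  feats <- survival_feature_set(state$cox_fit)
  feats <- intersect(feats, colnames(X))
  Xs <- X[, feats, drop = FALSE]
  ch <- choose_k_silhouette(Xs, k_min, k_max, seed = seed, n_restarts = n_restarts)
  lr <- logrank_test(dataset$survival$time_days, dataset$survival$event, ch$labels)
  km <- kaplan_meier(dataset$survival$time_days, dataset$survival$event, ch$labels)
  structure(list(labels = stats::setNames(ch$labels, dataset$patient_ids),
                 k = ch$k, silhouette_by_k = ch$silhouette_by_k,
                 logrank = lr, km_curves = km, feature_ids = feats, run = run),
            class = "subtype_result")
}

#' @export
print.subtype_result <- function(x, ...) {
  cat(sprintf("subtype_result: K = %d (silhouette %.3f), log-rank chi2 = %.2f (p = %.3g), %d survival features, run %d\n",
              x$k, x$silhouette_by_k[as.character(x$k)], x$logrank$chi_square,
              x$logrank$p_value, length(x$feature_ids), x$run))
  invisible(x)
}
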