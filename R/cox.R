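# Cox proportional-hazards machinery: Breslow partial likelihood, a small
# multivariate Newton solver (used as an in-package unregularized oracle),
# and a vectorized univariate screening engine.

revcumsum <- function(x) rev(cumsum(rev(x)))

# Shared sorted structure for partial-likelihood computations. Patients are
# sorted by ascending time; each position records the first index of its
# tie group, so reverse cumulative sums evaluated there cover the Breslow
# risk set {j : t_j >= t_i} including ties.
cox_structure <- function(time, event) {
  ord <- order(time)
  ts <- time[ord]
  es <- event[ord] != 0
  gstart <- match(ts, ts)  # first index of each tie group
  list(ord = ord, time = ts, event = es, gstart = gstart,
       evt = which(es), gs_evt = gstart[es])
}

#' Breslow Cox partial log-likelihood
#'
#' @param X patients x p covariate matrix (or a vector for p = 1).
#' @param time,event survival times and event indicators.
#' @param beta coefficient vector.
#' @return the log partial likelihood under Breslow tie handling.
#' @export
cox_partial_loglik <- function(X, time, event, beta) {
  X <- as.matrix(X)
  st <- cox_structure(time, event)
  eta <- drop(X[st$ord, , drop = FALSE] %*% beta)
  eta <- eta - max(eta)  # invariant shift, guards exp overflow
  S0 <- revcumsum(exp(eta))
  sum(eta[st$evt] - log(S0[st$gs_evt]))
}

# Score vector and observed information at beta (multivariate, Breslow).
cox_score_info <- function(Xs, st, beta) {
  p <- ncol(Xs)
  eta <- drop(Xs %*% beta)
  shift <- max(eta)
  w <- exp(eta - shift)
  S0 <- revcumsum(w)
  S1 <- apply(Xs * w, 2, revcumsum)
  score <- numeric(p)
  info <- matrix(0, p, p)
  gs <- st$gs_evt
  den <- S0[gs]
  xbar <- S1[gs, , drop = FALSE] / den
  score <- colSums(Xs[st$evt, , drop = FALSE] - xbar)
  # information: sum_events S2/S0 - xbar xbar^T, with S2 the risk-set sum of
  # outer products; accumulate via per-pair reverse cumsums (p is small here)
  for (a in seq_len(p)) {
    for (b in a:p) {
      S2ab <- revcumsum(w * Xs[, a] * Xs[, b])
      v <- sum(S2ab[gs] / den - xbar[, a] * xbar[, b])
      info[a, b] <- v
      info[b, a] <- v
    }
  }
  list(score = score, info = info)
}

#' Unpenalized Cox fit by Newton-Raphson (Breslow ties)
#'
#' Small-p reference solver: starts at zero, takes Newton steps with
#' step-halving on partial-likelihood decrease, stops when the score norm
#' drops below `tol` or after `max_iter` iterations.
#'
#' @param X patients x p covariate matrix.
#' @param time,event survival data.
#' @param tol convergence tolerance on the score norm.
#' @param max_iter iteration cap.
#' @return list with `beta`, `se` (inverse observed information),
#'   `loglik`, `iter`, `converged`.
#' @export
cox_newton <- function(X, time, event, tol = 1e-8, max_iter = 50) {
  X <- as.matrix(X)
  if (sum(event != 0) < 2) stopf("screening error: fewer than 2 events")
  Xc <- sweep(X, 2, colMeans(X))  # centering leaves the fit invariant
  st <- cox_structure(time, event)
  Xs <- Xc[st$ord, , drop = FALSE]
  beta <- numeric(ncol(X))
  ll <- cox_partial_loglik(Xc, time, event, beta)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    si <- cox_score_info(Xs, st, beta)
    if (sqrt(sum(si$score^2)) < tol) {converged <- TRUE; break}
    step <- drop(solve(si$info, si$score))
    for (h in 0:20) {
      cand <- beta + step / 2^h
      ll_new <- cox_partial_loglik(Xc, time, event, cand)
      if (ll_new >= ll - 1e-12) break
    }
    beta <- cand
    ll <- ll_new
  }
  si <- cox_score_info(Xs, st, beta)
  se <- sqrt(diag(solve(si$info)))
  list(beta = beta, se = se, loglik = ll, iter = it, converged = converged)
}

# Univariate Newton fit on a pre-sorted centered covariate. Returns the
# estimate, SE, log-likelihoods at 0 and at the optimum, and a monotone-
# likelihood flag when |beta| escapes the cap (perfect separation).
cox_uni_newton <- function(xs, st, cap = 20, tol = 1e-8, max_iter = 50) {
  evt <- st$evt
  gs <- st$gs_evt
  eval_at <- function(beta) {
    w <- exp(beta * xs)
    S0 <- revcumsum(w)
    S1 <- revcumsum(w * xs)
    S2 <- revcumsum(w * xs * xs)
    den <- S0[gs]
    xbar <- S1[gs] / den
    list(ll = sum(beta * xs[evt] - log(den)),
         score = sum(xs[evt] - xbar),
         info = sum(S2[gs] / den - xbar^2))
  }
  beta <- 0
  e0 <- eval_at(0)
  ll0 <- e0$ll
  e <- e0
  monotone <- FALSE
  for (it in seq_len(max_iter)) {
    if (abs(e$score) < tol) break
    if (e$info <= 0) {monotone <- TRUE; break}
    step <- e$score / e$info
    cand <- beta + step
    ecand <- eval_at(cand)
    h <- 0
    while (ecand$ll < e$ll - 1e-12 && h < 20) {
      h <- h + 1
      cand <- beta + step / 2^h
      ecand <- eval_at(cand)
    }
    beta <- cand
    e <- ecand
    if (abs(beta) >= cap) {monotone <- TRUE; beta <- sign(beta) * cap; e <- eval_at(beta); break}
  }
  se <- if (e$info > 0) 1 / sqrt(e$info) else NA_real_
  list(beta = beta, se = se, loglik = e$ll, loglik0 = ll0, monotone = monotone)
}

#' Univariate Cox-Wald screening of a feature matrix
#'
#' Fits a univariate Cox proportional-hazards model (Breslow ties, Newton
#' iterations started at zero with step-halving) to every feature and
#' reports the Wald test. Constant features are flagged and given p = 1;
#' features whose likelihood is monotone (estimate escaping the +/-20 cap)
#' are flagged with a floored p-value, and flagged features are never
#' selected downstream.
#'
#' @param X patients x features matrix (no missing values; screen after
#'   imputation/scaling).
#' @param time,event survival data; at least 2 events required.
#' @return data.frame with columns `feature`, `beta`, `se`, `z`, `p`,
#'   `loglik`, `loglik0`, `flag` ("ok", "constant" or "monotone").
#' @export
cox_screen <- function(X, time, event) {
  X <- as.matrix(X)
  if (sum(event != 0) < 2) stopf("screening error: fewer than 2 events")
  st <- cox_structure(time, event)
  p <- ncol(X)
  fid <- colnames(X) %||% as.character(seq_len(p))
  out <- data.frame(feature = fid, beta = 0, se = NA_real_, z = NA_real_,
                    p = 1, loglik = NA_real_, loglik0 = NA_real_,
                    flag = "ok", stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    x <- X[, j]
    if (stats::sd(x) < 1e-12) {
      out$flag[j] <- "constant"
      next
    }
    xs <- (x - mean(x))[st$ord]
    fit <- cox_uni_newton(xs, st)
    out$beta[j] <- fit$beta
    out$se[j] <- fit$se
    out$loglik[j] <- fit$loglik
    out$loglik0[j] <- fit$loglik0
    if (fit$monotone) {
      out$flag[j] <- "monotone"
      out$z[j] <- if (!is.na(fit$se)) fit$beta / fit$se else NA_real_
      out$p[j] <- 2e-16  # floored; excluded from selection anyway
    } else {
      out$z[j] <- fit$beta / fit$se
      out$p[j] <- 2 * stats::pnorm(-abs(out$z[j]))
    }
  }
  out
}

#' Select the top-k features by Wald p-value
#'
#' Returns up to `k` non-flagged feature ids sorted by ascending p-value;
#' ties are broken by descending `|z|`, then lexicographic feature id, so
#' selection is deterministic. If fewer than `k` usable features exist, all
#' are returned with a shortfall warning.
#'
#' @param screen result of [cox_screen()].
#' @param k per-modality cap (500 for mRNA/methylation, 300 for
#'   lncRNA/miRNA at full scale).
#' @return character vector of selected feature ids, in rank order.
#' @export
select_top_k <- function(screen, k) {
  if (!is.numeric(k) || k <= 0) stopf("k must be a positive integer")
  usable <- screen[screen$flag == "ok", , drop = FALSE]
  ord <- order(usable$p, -abs(usable$z), usable$feature)
  if (nrow(usable) < k) {
    warning(sprintf("only %d usable features for k = %d", nrow(usable), k), call. = FALSE)
  }
  usable$feature[ord][seq_len(min(k, nrow(usable)))]
}

#' Write a screening table as TSV
#' @param screen result of [cox_screen()].
#' @param selected character vector of selected ids.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(screen, selected, path) {
  screen$selected <- screen$feature %in% selected
  utils::write.table(screen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
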