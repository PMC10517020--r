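# Elastic-net regularized Cox model. Optimization is delegated to glmnet's
# coordinate descent; the penalty path, event-stratified cross-validation,
# and the cross-validated Harrell C-index selection criterion are this
# package's own, as is the CoxFit container the rest of the pipeline sees.

#' Score vector of the Breslow Cox partial log-likelihood
#'
#' Gradient of the log partial likelihood at `beta`; used for KKT
#' diagnostics of penalized fits.
#'
#' @param X patients x p covariate matrix.
#' @param time,event survival data.
#' @param beta coefficient vector.
#' @return numeric gradient of length p.
#' @export
cox_score <- function(X, time, event, beta) {
  X <- as.matrix(X)
  st <- cox_structure(time, event)
  Xs <- X[st$ord, , drop = FALSE]
  eta <- drop(Xs %*% beta)
  w <- exp(eta - max(eta))
  S0 <- revcumsum(w)
  S1 <- apply(Xs * w, 2, revcumsum)
  den <- S0[st$gs_evt]
  colSums(Xs[st$evt, , drop = FALSE]) - colSums(S1[st$gs_evt, , drop = FALSE] / den)
}

# Event-stratified fold assignment: events and censored patients are dealt
# round-robin into folds separately, so every fold carries events.
stratified_folds <- function(event, n_folds) {
  fold <- integer(length(event))
  for (grp in list(which(event != 0), which(event == 0))) {
    fold[sample(grp)] <- rep_len(seq_len(n_folds), length(grp))
  }
  fold
}

#' Fit an elastic-net Cox model with CV-selected penalty
#'
#' Searches a log-spaced path of 100 lambda values spanning two decades
#' below `lambda_max` (the smallest penalty with an all-zero solution).
#' The penalty strength is chosen to maximize the cross-validated Harrell
#' C-index over event-stratified folds (ties resolved toward the larger,
#' sparser lambda); the model is then refitted on the full training data at
#' the chosen lambda. Input columns are expected to be standardized
#' upstream; no internal rescaling is performed.
#'
#' @param X standardized patients x p matrix (embeddings + encoded
#'   clinical).
#' @param time,event training survival data; at least `n_folds` events.
#' @param alpha L1/L2 mixing weight (0.5 gives equal weight to both
#'   penalties).
#' @param n_folds number of CV folds.
#' @param seed RNG seed controlling fold assignment.
#' @param nlambda,lambda_decades path resolution and span.
#' @param lambda optional fixed penalty; skips cross-validation and fits at
#'   this value (still warm-started along the path).
#' @return object of class `cox_fit`: `coefficients` (named),
#'   `alpha`, `lambda`, `lambda_path`, `cv_curve`, `nonzero_ids`.
#' @export
fit_elastic_net_cox <- function(X, time, event, alpha = 0.5, n_folds = 5,
                                seed = 1L, nlambda = 100, lambda_decades = 2,
                                lambda = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%03d", seq_len(ncol(X)))
  n_events <- sum(event != 0)
  if (n_events == 0) stopf("no events in training data")
  if (n_events < 2 * n_folds) {
    n_folds <- max(2L, n_events %/% 2L)
    omicsurv_log("too few events; reducing CV folds to ", n_folds, verbose = TRUE)
  }
  y <- cbind(time = time, status = as.numeric(event != 0))

  lmax <- glmnet::glmnet(X, y, family = "cox", alpha = alpha,
                         standardize = FALSE, nlambda = 5)$lambda[1]
  path <- exp(seq(log(lmax), log(lmax) - lambda_decades * log(10),
                  length.out = nlambda))
  if (!is.null(lambda)) {
    # fixed-penalty fit, no CV; path still anchored at lambda_max for a
    # warm-started coordinate-descent solution
    path <- sort(unique(c(path[path > lambda], lambda)), decreasing = TRUE)
    full <- glmnet::glmnet(X, y, family = "cox", alpha = alpha,
                           standardize = FALSE, lambda = path)
    coefs <- drop(as.matrix(stats::coef(full, s = lambda, exact = FALSE)))
    names(coefs) <- colnames(X)
    return(structure(list(coefficients = coefs, alpha = alpha, lambda = lambda,
                          lambda_path = path, cv_curve = NULL,
                          nonzero_ids = names(coefs)[coefs != 0],
                          nonzero_by_lambda = colSums(as.matrix(full$beta) != 0),
                          n_folds = 0L),
                     class = "cox_fit"))
  }

  fold <- with_seed(seed, stratified_folds(event, n_folds))
  cvm <- matrix(NA_real_, n_folds, nlambda)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    fit_f <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr, , drop = FALSE],
                            family = "cox", alpha = alpha,
                            standardize = FALSE, lambda = path)
    lp <- stats::predict(fit_f, newx = X[!tr, , drop = FALSE], s = path)
    for (l in seq_len(ncol(lp))) {
      cvm[f, l] <- tryCatch(
        harrell_cindex(lp[, l], time[!tr], event[!tr])$c_index,
        error = function(e) NA_real_)
    }
  }
  cv_curve <- colMeans(cvm, na.rm = TRUE)
  cv_curve[is.nan(cv_curve)] <- NA_real_
  best <- which(cv_curve == max(cv_curve, na.rm = TRUE))[1]  # path descends: first = sparsest

  full <- glmnet::glmnet(X, y, family = "cox", alpha = alpha,
                         standardize = FALSE, lambda = path)
  coefs <- drop(as.matrix(stats::coef(full, s = path[best], exact = FALSE)))
  names(coefs) <- colnames(X)
  nz_path <- colSums(as.matrix(full$beta) != 0)
  structure(list(coefficients = coefs, alpha = alpha, lambda = path[best],
                 lambda_path = path, cv_curve = cv_curve,
                 nonzero_ids = names(coefs)[coefs != 0],
                 nonzero_by_lambda = nz_path, n_folds = n_folds),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("elastic-net Cox fit: alpha = %.2f, lambda = %.4g, %d/%d nonzero coefficients\n",
              x$alpha, x$lambda, length(x$nonzero_ids), length(x$coefficients)))
  invisible(x)
}

#' Linear-predictor risk scores from a fitted Cox model
#'
#' Returns `X %*% beta`; higher scores mean higher hazard (shorter expected
#' survival).
#'
#' @param fit a `cox_fit`.
#' @param X matrix whose columns match the fit's coefficients.
#' @return numeric risk score per patient.
#' @export
predict_risk <- function(fit, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(fit$coefficients)) {
    stopf("X has %d columns but the fit has %d coefficients",
          ncol(X), length(fit$coefficients))
  }
  drop(X %*% fit$coefficients)
}

#' Serialize a Cox fit to JSON
#' @param fit a `cox_fit`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_cox_fit <- function(fit, path) {
  jsonlite::write_json(
    list(coefficients = as.list(fit$coefficients), alpha = fit$alpha,
         lambda = fit$lambda, lambda_path = fit$lambda_path,
         cv_curve = fit$cv_curve),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
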