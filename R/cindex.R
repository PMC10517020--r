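# Harrell concordance index under right-censoring.
#
# Comparable pairs (Harrell's convention): (i, j) with t_i < t_j and patient
# i an observed event; plus equal-time pairs where exactly one of the two is
# an event (the event member is taken to die first). A pair is concordant
# when the earlier death carries the higher risk score; tied risk scores
# contribute 1/2. Equal-time event/event and censored/censored pairs are not
# comparable.

#' Harrell concordance index
#'
#' @param risk numeric per-patient risk scores (higher = shorter expected
#'   survival).
#' @param time,event survival times and event indicators.
#' @param method `"fast"` (O(n log n), Fenwick tree over risk ranks) or
#'   `"reference"` (O(n^2) pair enumeration). Both implement the identical
#'   convention and agree exactly.
#' @return object of class `concordance_result`: `c_index`,
#'   `n_concordant`, `n_discordant`, `n_tied_risk`, `n_comparable`.
#' @export
harrell_cindex <- function(risk, time, event, method = c("fast", "reference")) {
  method <- match.arg(method)
  stopifnot(length(risk) == length(time), length(time) == length(event))
  res <- if (method == "fast") cindex_fast(risk, time, event)
         else cindex_reference(risk, time, event)
  if (res$n_comparable == 0) stopf("undefined result: no comparable pairs")
  res$c_index <- (res$n_concordant + 0.5 * res$n_tied_risk) / res$n_comparable
  class(res) <- "concordance_result"
  res
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Harrell C-index: %.4f (%d concordant, %d discordant, %d tied of %d comparable pairs)\n",
              x$c_index, x$n_concordant, x$n_discordant, x$n_tied_risk, x$n_comparable))
  invisible(x)
}

cindex_reference <- function(risk, time, event) {
  ev <- event != 0
  n <- length(risk)
  conc <- disc <- tied <- 0
  for (i in which(ev)) {
    comp <- (time[i] < time) | (time[i] == time & !ev)
    comp[i] <- FALSE
    conc <- conc + sum(comp & risk[i] > risk)
    disc <- disc + sum(comp & risk[i] < risk)
    tied <- tied + sum(comp & risk[i] == risk)
  }
  list(n_concordant = conc, n_discordant = disc, n_tied_risk = tied,
       n_comparable = conc + disc + tied)
}

# Fenwick (binary indexed) tree over risk ranks: prefix counts in O(log n).
fenwick_new <- function(n) numeric(n)
fenwick_add <- function(tree, i) {
  n <- length(tree)
  while (i <= n) {
    tree[i] <- tree[i] + 1
    i <- i + bitwAnd(i, -i)
  }
  tree
}
fenwick_prefix <- function(tree, i) {  # count of ranks <= i
  s <- 0
  while (i > 0) {
    s <- s + tree[i]
    i <- i - bitwAnd(i, -i)
  }
  s
}

cindex_fast <- function(risk, time, event) {
  ev <- event != 0
  n <- length(risk)
  rr <- match(risk, sort(unique(risk)))  # dense risk ranks
  nr <- max(rr)
  tree <- fenwick_new(nr)
  inserted <- 0
  conc <- disc <- tied <- 0
  ord <- order(-time)
  i <- 1
  while (i <= n) {
    # tie group of equal times
    j <- i
    while (j < n && time[ord[j + 1]] == time[ord[i]]) j <- j + 1
    grp <- ord[i:j]
    g_ev <- grp[ev[grp]]
    g_cs <- grp[!ev[grp]]
    for (k in g_ev) {
      below <- fenwick_prefix(tree, rr[k] - 1)
      at <- fenwick_prefix(tree, rr[k]) - below
      conc <- conc + below
      tied <- tied + at
      disc <- disc + (inserted - below - at)
      if (length(g_cs)) {  # equal-time event vs censored pairs
        conc <- conc + sum(risk[k] > risk[g_cs])
        disc <- disc + sum(risk[k] < risk[g_cs])
        tied <- tied + sum(risk[k] == risk[g_cs])
      }
    }
    for (k in grp) tree <- fenwick_add(tree, rr[k])
    inserted <- inserted + length(grp)
    i <- j + 1
  }
  list(n_concordant = conc, n_discordant = disc, n_tied_risk = tied,
       n_comparable = conc + disc + tied)
}
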