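#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic entry points route through
# this so identical (config, seed) pairs are bit-reproducible and independent
# of surrounding RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a child seed from a base seed and a stage label; keeps every stage's
# stream distinct yet reproducible. Result stays below 2^31 - 1.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.double(seed) * 48271 + h) %% 2147483629L)
}

omicsurv_log <- function(..., verbose = getOption("omicsurv.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[omicsurv] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 1 && x == floor(x)

is_fraction <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
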