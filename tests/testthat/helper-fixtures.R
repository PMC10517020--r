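# Shared fixtures, built in code and cached per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small but fully structured multimodal dataset used across modules.
small_gen <- function() {
  cached("small_gen", {
    cfg <- sim_config(n_patients = 300,
                      features_per_modality = c(mrna = 200, mirna = 60,
                                                lncrna = 80, methylation = 300),
                      seed = 42)
    generate_dataset(cfg)
  })
}

# Fast pipeline configuration sized for unit tests (caps divisible by 10 so
# early and late bottleneck widths agree).
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_runs = 2,
         lfs_caps = c(mrna = 50, methylation = 50, lncrna = 30, mirna = 30),
         ae = list(max_epochs = 10), n_folds = 3),
    list(...))
  do.call(experiment_config, args)
}

# Weibull survival with independent exponential censoring, for unit tests
# that need survival data without the full generator.
simulate_simple_surv <- function(n, lp = rep(0, n), shape = 1.2, scale = 1000,
                                 cens_rate = NULL) {
  T <- scale * (rexp(n) / exp(lp))^(1 / shape)
  if (is.null(cens_rate)) {
    data.frame(time = T, event = rep(1L, n))
  } else {
    C <- rexp(n, cens_rate)
    data.frame(time = pmin(T, C), event = as.integer(T <= C))
  }
}
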