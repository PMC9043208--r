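# Shared fixtures. Heavy objects (the acceptance cohort and its trained
# models) are computed once per test run and cached.

.fqrs_cache <- new.env(parent = emptyenv())

cache_get <- function(key, fn) {
  if (!exists(key, envir = .fqrs_cache)) assign(key, fn(), envir = .fqrs_cache)
  get(key, envir = .fqrs_cache)
}

# A small clean recording used by several unit tests.
fixture_recording <- function(seed = 42, ...) {
  cache_get(paste0("rec", seed, paste(c(...), collapse = "_")), function()
    gen_recording(synthetic_config(seed = seed, ...)))
}

fixture_preprocessed <- function(seed = 42, ...) {
  cache_get(paste0("pre", seed, paste(c(...), collapse = "_")), function()
    preprocess(fixture_recording(seed, ...)$ecg))
}

# One strip containing `n_beats` copies of a beat, for single-lead tests.
beat_strip <- function(beat, n_beats = 3, rr_s = 1, fs = beat$fs) {
  n <- round((n_beats + 0.5) * rr_s * fs)
  x <- numeric(n)
  rs <- round((seq_len(n_beats) - 0.5) * rr_s * fs)
  for (r in rs) {
    idx <- r + seq_along(beat$wave) - beat$r_idx
    keep <- idx >= 1 & idx <= n
    x[idx[keep]] <- x[idx[keep]] + beat$wave[keep]
  }
  list(x = x, rpeaks = rs, fs = fs)
}

# Crop a beat to its true QRS support as a normalized complex.
beat_qrs <- function(beat) qrs_complex(beat$wave[beat$onset:beat$offset],
                                       beat$fs)

# Brute-force O(n^2) oracle for the quality filter: explicit pairwise
# Pearson correlations, count-below-q rule, self-correlation included.
quality_filter_oracle <- function(mat, q = 0.85) {
  n <- nrow(mat)
  keep <- logical(n)
  for (i in seq_len(n)) {
    below <- 0L
    for (j in seq_len(n)) {
      r <- suppressWarnings(stats::cor(mat[i, ], mat[j, ]))
      if (!is.finite(r) || r < 0) r <- 0
      if (r < q) below <- below + 1L
    }
    keep[i] <- below <= n / 2
  }
  keep
}

# Exhaustive concordant-pair ROC AUC oracle (ties count 1/2).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# The acceptance cohort (criteria 6-8): 300 recordings, prevalence 0.3,
# 20% ambiguous fragmented leads, defaults elsewhere. Feature extraction
# dominates the cost, so it is cached together with the experiment run.
acceptance_cohort_features <- function() {
  cache_get("acc_ft", function() {
    cohort <- gen_cohort(n_recordings = 300, fqrs_prevalence = 0.3,
                         ambiguity_frac = 0.2, seed = 20260909L)
    ft <- cohort_features(cohort)
    list(cohort = cohort, ft = ft)
  })
}

acceptance_experiment <- function() {
  cache_get("acc_exp", function() {
    ft <- acceptance_cohort_features()$ft
    run_experiment(ft, kernels = c("linear", "rbf"), n_repeats = 10,
                   seed = 20260909L)
  })
}
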