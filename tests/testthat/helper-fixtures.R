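# Shared fixtures, built once per test run and memoised. All fixtures
# are generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# small jitter-free cohort for detector/feature ground-truth checks
small_clean_cohort <- function() fixture("small_clean", function()
  generate_cohort(2, seed = 5, duration = 10, jitter = jitter_off()))

# small jittered cohort for evaluation plumbing tests
small_cohort <- function() fixture("small", function()
  generate_cohort(4, seed = 7, duration = 10))

small_features <- function() fixture("small_feats", function()
  cohort_features(small_cohort()))

# the full study-scale cohort (22 subjects per class) used by the
# end-to-end and noise-robustness checks
study_cohort <- function() fixture("study", function()
  generate_cohort(22, seed = 1, duration = 10))

study_features <- function() fixture("study_feats", function()
  cohort_features(study_cohort()))

# three-class Gaussian blobs in 4-D, well separated and non-collinear
# (so every one-vs-rest split is linearly separable); for classifier
# capacity checks
blob_features <- function(n_per_class = 15, sep = 4, seed = 42) {
  set.seed(seed)
  centers <- rbind(c(0, 0, 0, 0), c(sep, 0, sep, 0), c(0, sep, 0, sep))
  X <- do.call(rbind, lapply(1:3, function(k)
    matrix(stats::rnorm(n_per_class * 4, sd = 1), n_per_class, 4) +
      matrix(centers[k, ], n_per_class, 4, byrow = TRUE)))
  data.frame(subject_id = sprintf("b%02d", seq_len(3 * n_per_class)),
             d1 = X[, 1], d2 = X[, 2], d3 = X[, 3], d4 = X[, 4],
             class = rep(1:3, each = n_per_class))
}

# steady-state amplitude of a filtered unit tone, measured over whole
# cycles in the second half of the signal
tone_gain <- function(freq, spec = filter_spec(), dur = 4) {
  t <- seq(0, dur - 1 / spec$fs, by = 1 / spec$fs)
  y <- butterworth_lowpass(sin(2 * pi * freq * t), spec)
  n_cyc <- floor(freq * dur / 2)
  tail_idx <- t >= (dur - n_cyc / freq)
  sqrt(2 * mean(y[tail_idx]^2))
}
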