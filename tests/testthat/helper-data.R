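# Shared fixtures, generated once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Small trimmed dataset with moderate emotion structure.
small_dataset <- function() fixture("small_ds", function()
  trim_dataset(generate_dataset(2, 6, seed = 42, effect_size = 1,
                                n_samples = 4096)))

# One full-geometry trial (40 x 8064).
full_trial <- function() fixture("full_trial", function()
  generate_dataset(1, 1, seed = 9, effect_size = 1)$trials[[1]])

# Reduced-scale study datasets for the deep-learning checks: 4 subjects x
# 10 trials, trimmed, at the two effect sizes used by the evaluation.
study_dataset <- function(effect_size) {
  nm <- paste0("study_es", effect_size)
  fixture(nm, function()
    trim_dataset(generate_dataset(4, 10, seed = 11, effect_size = effect_size)))
}

# Normalized augmented EEG view of a study dataset plus labels and a
# grouped train/test split (no trial straddles the split).
augmented_study <- function(effect_size, scale = "arousal") {
  nm <- paste0("aug_es", effect_size, "_", scale)
  fixture(nm, function() {
    ds <- study_dataset(effect_size)
    aug <- normalize_channels(augment_by_channel(ds, "eeg"))
    y <- augmented_labels(aug, ds, scale)
    grp <- paste(aug$origin$subject, aug$origin$trial)
    fold <- affectsda:::make_folds(y, 4, seed = 77, groups = grp)
    list(x = aug$instances, y = y, test = fold == 1, origin = aug$origin)
  })
}

# A deterministic quadratically phase-coupled three-tone signal.
qpc_signal <- function(seed = 5, amplitude = 1.5, n = 3840, fs = 128) {
  with_seed_test(seed, {
    t <- (seq_len(n) - 1) / fs
    p1 <- stats::runif(1, 0, 2 * pi)
    p2 <- stats::runif(1, 0, 2 * pi)
    amplitude * (cos(2 * pi * 15 * t + p1) + cos(2 * pi * 10 * t + p2) +
                   cos(2 * pi * 25 * t + p1 + p2)) + 0.1 * stats::rnorm(n)
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
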