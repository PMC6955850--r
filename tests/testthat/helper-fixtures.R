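# Shared fixtures, built once per test run and cached. The expensive
# datasets and cross-validation runs are reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# small smooth dataset on a coarse mesh, for fast unit tests
small_dataset <- function() {
  fixture("small_dataset", function() {
    generate_dataset(sample_designs(design_space(), 30, seed = 101L),
                     synthetic_config(n_nodes = 152L))  # 152 = 15*10 + 2
  })
}

# the default-condition dataset used by the acceptance checks:
# >= 500 designs, default 1381-node mesh, noise-free
default_dataset <- function() {
  fixture("default_dataset", function() {
    generate_dataset(sample_designs(design_space(), 500, seed = 20260101L),
                     synthetic_config())
  })
}

# low-rank oracle dataset (fields are exact combinations of 8 fixed modes)
lowrank_dataset <- function() {
  fixture("lowrank_dataset", function() {
    generate_dataset(sample_designs(design_space(), 200, seed = 777L),
                     synthetic_config(low_rank = TRUE))
  })
}

# training schedule used by the cross-validation checks (documented package
# choice: plain Adamax phases, batch 32, Keras-default optimizer settings)
cv_train_cfg <- function(seed = 0L) {
  train_config(epochs = 60L, batch_size = 32L, seed = seed)
}

cv_epochs_a <- c(ae = 45L, map = 800L, finetune = 35L)

# cached Monte-Carlo CV runs on the default dataset
cached_cv <- function(family, target, rho = 90, repeats = 10L, seed = 1L) {
  key <- paste("cv", family, target, rho, repeats, seed, sep = "_")
  fixture(key, function() {
    monte_carlo_cv(default_dataset(), family = family, target = target,
                   rho = rho, repeats = repeats, seed = seed,
                   cfg = cv_train_cfg(), epochs_a = cv_epochs_a)
  })
}

# naive loop-based re-implementations of the error metrics (independent
# oracles for the vectorized package code)
naive_shape_errors <- function(truth, pred, R) {
  n <- nrow(truth)
  d <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- sqrt(sum((truth[i, ] - pred[i, ])^2))
  }
  list(mean_e = sum(d) / n, n_mean_e = sum(d) / n / R * 100,
       max_e = max(d), n_max_e = max(d) / R * 100)
}

naive_stress_errors <- function(truth, pred) {
  n <- length(truth)
  s <- 0
  for (i in seq_len(n)) s <- s + abs(truth[i] - pred[i])
  mean_e <- s / n
  rng <- max(truth) - min(truth)
  max_e <- abs(max(abs(truth)) - max(abs(pred)))
  list(mean_e = mean_e, n_mean_e = mean_e / rng * 100,
       max_e = max_e, n_max_e = max_e / max(abs(truth)) * 100)
}
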