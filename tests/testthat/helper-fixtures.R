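# Shared fixtures. Everything is generated in code; the heavy desk-scale
# ensembles are trained once per session and memoised so that every test
# file (and the acceptance checks) reuses the same objects.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = fixture_cache, inherits = FALSE)) {
    assign(key, builder(), envir = fixture_cache)
  }
  get(key, envir = fixture_cache, inherits = FALSE)
}

# ---- tiny fixtures for unit tests -----------------------------------------

# 400-sample records (100 Hz, 4 s): long enough for rhythm and tone
# structure, cheap enough for per-test training.
tiny_generator_config <- function(seed = 1L) {
  ecg_generator_config(sampling_rate = 100, duration = 4, seed = seed)
}

tiny_batch <- function(n_per_class = 6L, seed = 1L) {
  memo(sprintf("tiny_batch_%d_%d", n_per_class, seed), function() {
    generate_dataset(n_per_class, tiny_generator_config(seed))
  })
}

tiny_spec <- function(seed = 1L, ...) {
  classifier_spec(1L, 4L, feature_dim = 8L, conv_widths = c(8L, 16L),
                  kernel_sizes = c(7L, 7L), strides = c(4L, 4L),
                  seed = seed, ...)
}

tiny_model <- function(seed = 1L, ...) init_classifier(tiny_spec(seed, ...))

# A small trained model on the tiny fixture (shared by attack tests).
tiny_trained <- function(seed = 1L) {
  memo(sprintf("tiny_trained_%d", seed), function() {
    b <- tiny_batch(50L, seed)
    sp <- split_batch(b, 0.8, seed = seed)
    res <- train_plain(tiny_model(seed), sp$train,
                       train_config(epochs = 12L, batch_size = 16L,
                                    learning_rate = 3e-3,
                                    seed = seed + 100L))
    list(model = res$model, trace = res$trace, train = sp$train,
         test = sp$test)
  })
}

# ---- desk-scale fixtures (the study conditions) ---------------------------
# n_per_class = 250, fs = 100 Hz, 10 s records, K = 3, 10 epochs.

desk_config <- function(kind, seed) {
  experiment_config(
    dataset = list(n_per_class = 250L),
    ensemble = list(k = 3L, epochs = 10L,
                    decorrelation = kind %in% c("dec", "decpart"),
                    partition = kind == "decpart"),
    attack = list(methods = "pgd", epsilons = 0.1, steps = 20L,
                  mode = "ensemble_alternating"),
    seed = seed)
}

desk_trained <- function(kind, seed) {
  memo(sprintf("desk_%s_%d", kind, seed), function() {
    run_training_pipeline(desk_config(kind, seed))
  })
}

desk_attacked <- function(kind, seed, epsilon = 0.1) {
  memo(sprintf("desk_attacked_%s_%d_%g", kind, seed, epsilon), function() {
    tr <- desk_trained(kind, seed)
    acfg <- attack_config(epsilon = epsilon, n_steps = 20L,
                          domain_bounds = c(-1, 1),
                          target_mode = "ensemble_alternating")
    pgd_attack(tr$ensemble, tr$data$test, acfg)
  })
}

# ---- shared oracles --------------------------------------------------------

# Mean squared column-wise correlation between two feature matrices
# (constant columns dropped: dead ReLU units carry no correlation signal).
mean_sq_feature_correlation <- function(z0, z1) {
  keep0 <- apply(z0, 2L, stats::sd) > 1e-12
  keep1 <- apply(z1, 2L, stats::sd) > 1e-12
  cc <- stats::cor(z0[, keep0, drop = FALSE], z1[, keep1, drop = FALSE])
  mean(cc^2)
}

# Independent least-squares oracle: solves the normal equations column by
# column and accumulates squared residuals.
oracle_lr_loss <- function(z1, z2, eps) {
  x <- cbind(z1, 1)
  xtx <- t(x) %*% x
  ssres <- 0
  for (j in seq_len(ncol(z2))) {
    beta <- solve(xtx, t(x) %*% z2[, j])
    ssres <- ssres + sum((z2[, j] - x %*% beta)^2)
  }
  sstot <- sum(sweep(z2, 2, colMeans(z2))^2)
  log(sstot + eps) - log(ssres + eps)
}

# Literal double-sum mutual-information oracle.
oracle_mutual_information <- function(p) {
  k <- nrow(p); c_dim <- ncol(p)
  mean_p <- colMeans(p)
  h_mean <- 0
  for (c in seq_len(c_dim)) {
    if (mean_p[c] > 0) h_mean <- h_mean - mean_p[c] * log(mean_p[c])
  }
  inner <- 0
  for (kk in seq_len(k)) for (c in seq_len(c_dim)) {
    if (p[kk, c] > 0) inner <- inner + p[kk, c] * log(p[kk, c])
  }
  h_mean + inner / k
}

# Brute-force counting oracle for the threshold metrics.
oracle_threshold_metrics <- function(correct, i_norm, i_t) {
  certain <- i_norm <= i_t
  n_cc <- sum(correct & certain)
  n_iu <- sum(!correct & !certain)
  list(rcc = if (sum(certain) == 0) 1 else n_cc / sum(certain),
       riu = if (sum(!correct) == 0) 1 else n_iu / sum(!correct),
       ua = (n_cc + n_iu) / length(correct))
}

# Random member-probability matrix (rows on the simplex).
random_prob_rows <- function(k, c_dim) {
  p <- matrix(stats::rexp(k * c_dim), k, c_dim)
  p / rowSums(p)
}

# Simple argmax-over-window peak picker, independent of the generator
# internals: local maxima above a height threshold, separated by a minimum
# gap.
pick_peaks <- function(x, min_gap, height = 0.5 * max(x)) {
  n <- length(x)
  cand <- which(x > height)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[x[cand] >= x[cand - 1] & x[cand] >= x[cand + 1]]
  peaks <- integer(0)
  for (p in cand) {
    if (length(peaks) == 0L || p - peaks[length(peaks)] >= min_gap) {
      peaks <- c(peaks, p)
    } else if (x[p] > x[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- p
    }
  }
  peaks
}

# The 6-record worked toy set used across the metric tests.
toy_records <- function() {
  tibble::tibble(
    record_id = sprintf("r%d", 1:6),
    correct = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    I_norm = c(0.1, 0.9, 0.2, 0.8, 0.4, 0.6))
}
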