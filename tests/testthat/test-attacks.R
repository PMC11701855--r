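test_that("the alternating-target schedule is i mod K", {
  expect_equal(alternating_target_schedule(0:5, 3L), c(0L, 1L, 2L, 0L, 1L, 2L))
  counts <- table(alternating_target_schedule(0:19, 3L))
  expect_equal(unname(c(counts)), c(7L, 7L, 6L))
  expect_equal(alternating_target_schedule(0:9, 1L), rep(0L, 10L))
})

test_that("kernel banks are normalized, symmetric and correctly sized", {
  pb <- physionet_kernel_bank()
  cb <- cpsc_kernel_bank()
  expect_equal(pb$m, 5L)
  expect_equal(cb$m, 5L)
  expect_equal(pb$widths, c(5L, 7L, 11L, 15L, 19L))
  expect_equal(cb$sigmas, c(5, 7, 10, 13, 17))
  for (bank in list(pb, cb)) {
    for (j in seq_len(bank$m)) {
      k <- bank$kernels[[j]]
      expect_length(k, bank$widths[j])
      expect_lt(abs(sum(k) - 1), 1e-9)
      expect_equal(k, rev(k), tolerance = 1e-15)
    }
  }
  expect_error(build_kernel_bank(4L, 1), class = "decorrens_domain_error")
  expect_error(build_kernel_bank(5L, -1), class = "decorrens_domain_error")
  expect_error(build_kernel_bank(c(5L, 7L), 1), class = "decorrens_domain_error")
})

test_that("zero-radius and zero-step attacks are exact identities", {
  tt <- tiny_trained(1L)
  b <- subset_batch(tt$test, 1:4)
  for (cfg in list(attack_config(epsilon = 0, alpha = 1, n_steps = 20L),
                   attack_config(epsilon = 0.1, n_steps = 0L))) {
    expect_identical(pgd_attack(tt$model, b, cfg)$signals, b$signals)
    expect_identical(sap_attack(tt$model, b, cfg)$signals, b$signals)
  }
})

test_that("one-step PGD on a linear-softmax model matches the closed form", {
  set.seed(21)
  c_dim <- 3L; ch <- 2L; t_len <- 15L
  w <- matrix(rnorm(ch * t_len * c_dim), ch * t_len, c_dim)
  bb <- rnorm(c_dim)
  model <- linear_softmax(w, bb, ch, t_len)
  x <- array(runif(2 * ch * t_len, -0.5, 0.5), c(2, ch, t_len))
  y <- c(0L, 2L)
  batch <- signal_batch(x, y, c("a", "b"), 10, n_classes = c_dim)
  cfg <- attack_config(epsilon = 0.05, alpha = 0.02, n_steps = 1L,
                       target_mode = "single_model")
  got <- pgd_attack(model, batch, cfg)$signals
  # closed form: grad_x CE = W (softmax - onehot) / N, reshaped per record
  expected <- x
  for (i in 1:2) {
    v <- as.vector(x[i, , ])
    logits <- drop(v %*% w) + bb
    p <- exp(logits - max(logits)); p <- p / sum(p)
    e <- p; e[y[i] + 1] <- e[y[i] + 1] - 1
    g <- matrix(w %*% e, ch, t_len)          # per-record gradient direction
    step <- x[i, , ] + cfg$alpha * sign(g)
    expected[i, , ] <- pmin(pmax(step, x[i, , ] - cfg$epsilon),
                            x[i, , ] + cfg$epsilon)
  }
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("attacks respect the epsilon ball and domain bounds", {
  tt <- tiny_trained(1L)
  b <- subset_batch(tt$test, 1:6)
  ens <- new_ensemble(list(tt$model, tiny_model(2L), tiny_model(3L)))
  set.seed(31)
  for (rep in 1:30) {
    eps <- runif(1, 0, 0.3)
    cfg <- attack_config(
      epsilon = eps, alpha = runif(1, 0.1, 2) * max(eps, 1e-6) / 10,
      n_steps = sample(0:6, 1),
      domain_bounds = if (runif(1) < 0.5) c(-1, 1) else NULL,
      target_mode = sample(c("single_model", "ensemble_alternating"), 1),
      target_index = sample(0:2, 1))
    method <- sample(c("pgd", "sap"), 1)
    out <- craft_attack(method, ens, b, cfg,
                        bank = build_kernel_bank(c(3L, 5L), c(1, 2)))
    delta <- out$signals - b$signals
    if (method == "pgd") expect_lte(max(abs(delta)), eps + 1e-9)
    if (!is.null(cfg$domain_bounds)) {
      expect_true(all(out$signals >= -1 - 1e-12 & out$signals <= 1 + 1e-12))
    }
  }
})

test_that("SAP smoothing preserves constants away from nothing (reflect pad)", {
  bank <- build_kernel_bank(c(5L, 9L), c(1.5, 3))
  s <- decorrens:::sap_smoother(bank, 60L)
  theta <- array(0.7, c(1, 1, 60))
  sm <- decorrens:::apply_time_operator(theta, s)
  # sum-normalized kernels + reflect padding preserve constants everywhere
  expect_lt(max(abs(sm - 0.7)), 1e-12)
})

test_that("one SAP step matches a literal direct-convolution oracle", {
  tt <- tiny_trained(1L)
  b <- subset_batch(tt$test, 1:3)
  bank <- build_kernel_bank(c(3L, 5L), c(1, 2))
  cfg <- attack_config(epsilon = 0.08, alpha = 0.008, n_steps = 1L,
                       target_mode = "single_model")
  got <- sap_attack(tt$model, b, cfg, bank)$signals

  # literal re-implementation with direct (non-operator) convolution
  reflect <- function(idx, n) {
    period <- 2L * (n - 1L)
    m <- (idx - 1L) %% period
    ifelse(m >= n, period - m, m) + 1L
  }
  direct_smooth <- function(v, bank) {
    n <- length(v)
    acc <- numeric(n)
    for (j in seq_len(bank$m)) {
      k <- bank$kernels[[j]]
      half <- (bank$widths[j] - 1L) / 2L
      out <- numeric(n)
      for (t in seq_len(n)) {
        idx <- reflect(t + seq(-half, half), n)
        out[t] <- sum(k * v[idx])
      }
      acc <- acc + out
    }
    acc / bank$m
  }
  x <- b$signals
  n_rec <- dim(x)[1]; t_len <- dim(x)[3]
  theta <- array(0, dim(x))
  # step 1: x'(0) = x, gradient of member CE at x, smoothed back onto theta
  g <- decorrens:::ce_input_gradient(tt$model, x, b$labels)$dx
  g_theta <- array(0, dim(x))
  for (i in seq_len(n_rec)) {
    # adjoint of reflect-padded convolution with a symmetric kernel equals
    # scatter-add; realized here literally via the transpose of the direct
    # convolution matrix
    s_mat <- matrix(0, t_len, t_len)
    for (t in seq_len(t_len)) {
      e <- numeric(t_len); e[t] <- 1
      s_mat[, t] <- direct_smooth(e, bank)
    }
    g_theta[i, 1, ] <- drop(t(s_mat) %*% g[i, 1, ])
  }
  theta <- pmin(pmax(theta + cfg$alpha * sign(g_theta), -cfg$epsilon),
                cfg$epsilon)
  expected <- x
  for (i in seq_len(n_rec)) {
    expected[i, 1, ] <- x[i, 1, ] + direct_smooth(theta[i, 1, ], bank)
  }
  expect_equal(got, expected, tolerance = 1e-5)
})

test_that("smoothed white noise loses high-frequency energy", {
  set.seed(41)
  bank <- physionet_kernel_bank()
  t_len <- 400L
  s <- decorrens:::sap_smoother(bank, t_len)
  theta <- array(rnorm(t_len), c(1, 1, t_len))
  smoothed <- decorrens:::apply_time_operator(theta, s)
  frac_high <- function(v) {
    spec <- Mod(stats::fft(v))^2
    half <- floor(t_len / 2)
    hi <- (floor(half / 2) + 1):half         # above fs / 4
    sum(spec[hi + 1]) / sum(spec[2:(half + 1)])
  }
  expect_lt(frac_high(smoothed[1, 1, ]), frac_high(theta[1, 1, ]))
})

test_that("single-model mode on a K = 1 ensemble equals attacking the bare model", {
  tt <- tiny_trained(1L)
  b <- subset_batch(tt$test, 1:4)
  cfg <- attack_config(epsilon = 0.1, n_steps = 5L,
                       target_mode = "single_model")
  ens <- new_ensemble(list(tt$model))
  expect_identical(pgd_attack(ens, b, cfg)$signals,
                   pgd_attack(tt$model, b, cfg)$signals)
  expect_identical(sap_attack(ens, b, cfg)$signals,
                   sap_attack(tt$model, b, cfg)$signals)
})

test_that("attack provenance is recorded", {
  tt <- tiny_trained(1L)
  b <- subset_batch(tt$test, 1:2)
  out <- pgd_attack(tt$model, b, attack_config(epsilon = 0.05, n_steps = 2L))
  prov <- attr(out, "provenance")
  expect_equal(prov$method, "pgd")
  expect_equal(prov$epsilon, 0.05)
  expect_equal(prov$steps, 2L)
})

test_that("attack configs validate their domain", {
  expect_error(attack_config(epsilon = -1), class = "decorrens_domain_error")
  expect_error(attack_config(epsilon = 1, alpha = 0),
               class = "decorrens_domain_error")
  expect_error(attack_config(epsilon = 1, n_steps = -1),
               class = "decorrens_domain_error")
})
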