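test_that("lr_loss matches the normal-equations oracle on random inputs", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(16:64, 1)
    d1 <- sample(2:8, 1); d2 <- sample(1:8, 1)
    z1 <- matrix(rnorm(n * d1), n, d1)
    z2 <- matrix(rnorm(n * d2), n, d2)
    eps <- sample(c(1e-5, 1e-3, 0.1), 1)
    expect_equal(lr_loss(z1, z2, eps), oracle_lr_loss(z1, z2, eps),
                 tolerance = 1e-6)
  }
})

test_that("an uninformative regressor gives zero loss", {
  set.seed(5)
  z1 <- matrix(0, 20, 3)
  z2 <- matrix(rnorm(20 * 4), 20, 4)
  # only the intercept is informative: SSres = SStot exactly
  expect_equal(lr_loss(z1, z2, 1e-5), 0, tolerance = 1e-10)
})

test_that("perfect linear dependence saturates the loss", {
  set.seed(6)
  z1 <- matrix(rnorm(30 * 3), 30, 3)
  w <- matrix(rnorm(3 * 2), 3, 2)
  z2 <- z1 %*% w
  eps <- 1e-5
  sstot <- sum(sweep(z2, 2, colMeans(z2))^2)
  expect_equal(lr_loss(z1, z2, eps), log(sstot + eps) - log(eps),
               tolerance = 1e-6)
})

test_that("with eps = 0, exp(-lr_loss) equals 1 - R^2 (Pearson)", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 40
    z1 <- matrix(rnorm(n * 3), n, 3)
    z2 <- 0.6 * z1[, 1] + rnorm(n)          # single-column regressand
    z2 <- matrix(z2, n, 1)
    val <- lr_loss(z1, z2, eps = 0)
    r2 <- summary(stats::lm(z2 ~ z1))$r.squared
    expect_equal(exp(-val), 1 - r2, tolerance = 1e-6)
  }
})

test_that("lr_loss is invariant to invertible transforms of the regressor", {
  set.seed(8)
  z1 <- matrix(rnorm(40 * 4), 40, 4)
  z2 <- matrix(rnorm(40 * 3), 40, 3)
  a <- matrix(rnorm(16), 4, 4) + diag(4) * 2  # well-conditioned invertible
  expect_equal(lr_loss(z1 %*% a, z2, eps = 0), lr_loss(z1, z2, eps = 0),
               tolerance = 1e-6)
})

test_that("rank-deficient regressors are handled without error", {
  set.seed(9)
  z1 <- matrix(rnorm(20 * 3), 20, 3)
  z1 <- cbind(z1, z1[, 1])                   # exactly collinear column
  z2 <- matrix(rnorm(20 * 2), 20, 2)
  expect_silent(v <- lr_loss(z1, z2, 1e-5))
  expect_true(is.finite(v))
  expect_equal(v, lr_loss(z1[, 1:3], z2, 1e-5), tolerance = 1e-8)
})

test_that("lr_loss enforces its contracts", {
  expect_error(lr_loss(matrix(0, 3, 2), matrix(0, 4, 2)),
               class = "decorrens_contract_error")
  expect_error(lr_loss(matrix(Inf, 4, 2), matrix(0, 4, 2)),
               class = "decorrens_contract_error")
})

test_that("randomized loss composes the audited pieces (forced draws)", {
  set.seed(11)
  n <- 40; d <- 6; r <- 3
  zk <- matrix(rnorm(n * d), n, d)
  zi <- matrix(rnorm(n * d), n, d)
  cfg <- decorr_config(projection_dim = r, stability_eps = 1e-5)
  for (s in c(21L, 22L, 23L, 24L)) {
    # replicate the internal draw order: swap coin, then projection
    set.seed(s)
    swap <- runif(1) < 0.5
    proj <- matrix(rnorm((d + 1) * r, sd = sqrt(1 / d)), d + 1, r)
    z1 <- if (swap) zi else zk
    z2 <- if (swap) zk else zi
    expected <- lr_loss(cbind(z1, 1) %*% proj, z2, cfg$stability_eps)
    set.seed(s)
    expect_equal(randomized_lr_loss(zk, zi, cfg), expected, tolerance = 1e-10)
  }
})

test_that("self-decorrelation is strictly positive", {
  set.seed(12)
  zk <- matrix(rnorm(50 * 6), 50, 6)
  cfg <- decorr_config(projection_dim = 3L)
  set.seed(1)
  expect_gt(randomized_lr_loss(zk, zk, cfg), 0)
})

test_that("the default projection has shape (D + 1) x r = 65 x 32", {
  set.seed(13)
  zk <- matrix(rnorm(80 * 64), 80, 64)
  zi <- matrix(rnorm(80 * 64), 80, 64)
  out <- decorrens:::randomized_lr_loss_impl(zk, zi, decorr_config())
  expect_equal(dim(out$projection), c(65L, 32L))
  expect_error(randomized_lr_loss(zk[, 1:8], zi[, 1:8],
                                  decorr_config(projection_dim = 32L)),
               class = "decorrens_contract_error")
})

test_that("randomized-loss gradients match finite differences", {
  set.seed(14)
  n <- 30; d <- 5; h <- 1e-6
  cfg <- decorr_config(projection_dim = 3L)
  zi <- matrix(rnorm(n * d), n, d)
  for (s in c(31L, 32L)) {                   # covers both swap branches
    zk <- matrix(rnorm(n * d), n, d)
    set.seed(s)
    out <- decorrens:::randomized_lr_loss_impl(zk, zi, cfg, want_grads = TRUE)
    for (idx in c(1L, 57L, n * d)) {
      f <- function(v) {
        z <- zk; z[idx] <- v
        set.seed(s)
        randomized_lr_loss(z, zi, cfg)
      }
      fd <- (f(zk[idx] + h) - f(zk[idx] - h)) / (2 * h)
      expect_equal(out$grad_zk[idx], fd, tolerance = 1e-4)
    }
  }
})

test_that("decorr_total_loss follows the lambda / k weighting", {
  set.seed(15)
  zk <- matrix(rnorm(40 * 6), 40, 6)
  z1 <- matrix(rnorm(40 * 6), 40, 6)
  z2 <- matrix(rnorm(40 * 6), 40, 6)
  cfg <- decorr_config(lambda_weight = 0.2, projection_dim = 3L)
  expect_identical(decorr_total_loss(1.37, zk, list(), cfg), 1.37)
  cfg0 <- decorr_config(lambda_weight = 0, projection_dim = 3L)
  expect_identical(decorr_total_loss(1.37, zk, list(z1, z2), cfg0), 1.37)
  set.seed(55)
  a <- randomized_lr_loss(zk, z1, cfg)
  b <- randomized_lr_loss(zk, z2, cfg)
  set.seed(55)
  expect_equal(decorr_total_loss(2.5, zk, list(z1, z2), cfg),
               2.5 + 0.2 * (a + b) / 2, tolerance = 1e-12)
})

test_that("misaligned record ids are rejected", {
  zk <- matrix(rnorm(20), 10, 2)
  attr(zk, "record_ids") <- sprintf("r%d", 1:10)
  zi <- matrix(rnorm(20), 10, 2)
  attr(zi, "record_ids") <- sprintf("r%d", 10:1)
  expect_error(decorr_total_loss(1, zk, list(zi),
                                 decorr_config(projection_dim = 1L)),
               class = "decorrens_contract_error")
})

test_that("feature caches agree with extract_features and round-trip", {
  tt <- tiny_trained(1L)
  cache <- build_feature_cache(tt$model, tt$train, model_index = 0L)
  ids <- tt$train$record_ids[c(5L, 2L, 9L)]
  rows <- cache_rows(cache, ids)
  z <- extract_features(tt$model, subset_batch(tt$train, c(5L, 2L, 9L)))
  expect_equal(rows, z, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(cache_rows(cache, "no_such_record"),
               class = "decorrens_contract_error")

  path <- withr::local_tempfile(fileext = ".rds")
  write_feature_cache(cache, path)
  cache2 <- read_feature_cache(path)
  expect_identical(cache2$values, cache$values)
  expect_true(file.exists(paste0(path, ".json")))

  # order independence: build from a shuffled batch, same mapping
  perm <- sample(n_records(tt$train))
  cache3 <- build_feature_cache(tt$model, subset_batch(tt$train, perm))
  expect_equal(cache_rows(cache3, ids), rows, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a decorrelated step with lambda = 0 equals the plain step bitwise", {
  b <- tiny_batch(4L)
  xb <- b$signals[1:8, , , drop = FALSE]
  yb <- b$labels[1:8]
  priors <- list(matrix(rnorm(8 * 8), 8, 8))
  m <- tiny_model(21L)
  opt <- decorrens:::adam_init(m$params)
  cfg0 <- decorr_config(lambda_weight = 0, projection_dim = 4L)
  set.seed(77)
  s1 <- decorrelated_training_step(m, xb, yb, priors, cfg0, opt, 1e-3)
  set.seed(77)
  s2 <- decorrelated_training_step(m, xb, yb, list(), decorr_config(), opt, 1e-3)
  expect_identical(s1$model$params, s2$model$params)
  expect_identical(s1$corr, 0)
})

test_that("the step's correlation component decomposes over prior models", {
  b <- tiny_batch(4L)
  idx <- 1:12
  xb <- b$signals[idx, , , drop = FALSE]
  yb <- b$labels[idx]
  m <- tiny_model(22L)
  cfg <- decorr_config(lambda_weight = 0.2, projection_dim = 4L)
  priors <- list(matrix(rnorm(12 * 8), 12, 8), matrix(rnorm(12 * 8), 12, 8))
  opt <- decorrens:::adam_init(m$params)
  set.seed(88)
  st <- decorrelated_training_step(m, xb, yb, priors, cfg, opt, 1e-3)
  set.seed(88)
  l1 <- randomized_lr_loss(st$features, priors[[1]], cfg)
  l2 <- randomized_lr_loss(st$features, priors[[2]], cfg)
  expect_equal(st$corr, (0.2 / 2) * (l1 + l2), tolerance = 1e-10)
})

test_that("batches smaller than r + 1 skip the decorrelation term", {
  b <- tiny_batch(2L)
  xb <- b$signals[1:4, , , drop = FALSE]
  yb <- b$labels[1:4]
  m <- tiny_model(23L)
  cfg <- decorr_config(projection_dim = 6L)  # 4 < 6 + 1
  opt <- decorrens:::adam_init(m$params)
  st <- decorrelated_training_step(m, xb, yb,
                                   list(matrix(rnorm(4 * 8), 4, 8)),
                                   cfg, opt, 1e-3)
  expect_true(st$skipped)
  expect_identical(st$corr, 0)
})

test_that("decorrelation training reduces cross-model feature correlation", {
  # stochastic, seeded: majority over 3 seeds at equal accuracy budget
  wins <- 0L
  for (seed in 1:3) {
    base <- desk_trained("baseline", seed)
    dec <- desk_trained("dec", seed)
    test <- base$data$test
    c_base <- mean_sq_feature_correlation(
      extract_features(base$ensemble$members[[1]], test),
      extract_features(base$ensemble$members[[2]], test))
    c_dec <- mean_sq_feature_correlation(
      extract_features(dec$ensemble$members[[1]], test),
      extract_features(dec$ensemble$members[[2]], test))
    if (c_dec < c_base) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("decorrelation adds modest wall-time overhead to an epoch", {
  b <- tiny_batch(25L)                       # 100 records
  m <- tiny_model(31L)
  cfg <- train_config(epochs = 2L, batch_size = 25L, seed = 3L)
  dec <- decorr_config(projection_dim = 4L)
  tt <- tiny_trained(1L)
  cache <- build_feature_cache(tt$model, b)
  t_plain <- system.time(train_plain(tiny_model(31L), b, cfg))[["elapsed"]]
  t_dec <- system.time(train_decorrelated(tiny_model(31L), b, cfg, dec,
                                          list(cache)))[["elapsed"]]
  expect_lt(t_dec, t_plain * 1.25 + 0.25)    # loose, hardware-tolerant bound
})
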