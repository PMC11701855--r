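test_that("threshold metrics reproduce the worked 6-record example", {
  tm <- threshold_metrics(toy_records(), 0.5)
  expect_equal(tm$rcc, 2 / 3)
  expect_equal(tm$riu, 2 / 3)
  expect_equal(tm$ua, 4 / 6)
  expect_false(tm$rcc_vacuous)
  expect_false(tm$riu_vacuous)
})

test_that("vacuous denominators return 1 and are flagged", {
  rec <- tibble::tibble(record_id = sprintf("r%d", 1:4),
                        correct = TRUE, I_norm = c(0.1, 0.2, 0.3, 0.4))
  tm <- threshold_metrics(rec, 0.5)
  expect_equal(c(tm$rcc, tm$riu, tm$ua), c(1, 1, 1))
  expect_true(tm$riu_vacuous)                # no incorrect records
  tm2 <- threshold_metrics(rec, 0.05)        # nothing certain either
  expect_true(tm2$rcc_vacuous)
  expect_error(threshold_metrics(rec[0, ], 0.5),
               class = "decorrens_contract_error")
})

test_that("a saturating threshold makes UA the accuracy", {
  set.seed(101)
  rec <- tibble::tibble(record_id = sprintf("r%d", 1:50),
                        correct = runif(50) < 0.7,
                        I_norm = runif(50))
  tm <- threshold_metrics(rec, max(rec$I_norm))
  expect_equal(tm$ua, mean(rec$correct))
  expect_equal(tm$riu, 0)
  expect_equal(tm$rcc, mean(rec$correct))
})

test_that("threshold metrics match the counting oracle on random sets", {
  set.seed(102)
  for (rep in 1:100) {
    n <- sample(1:40, 1)
    rec <- tibble::tibble(record_id = sprintf("r%d", seq_len(n)),
                          correct = runif(n) < runif(1),
                          I_norm = runif(n, -0.3, 1.4))
    i_t <- runif(1, -0.2, 1.2)
    got <- threshold_metrics(rec, i_t)
    oracle <- oracle_threshold_metrics(rec$correct, rec$I_norm, i_t)
    expect_identical(got$rcc, oracle$rcc)
    expect_identical(got$riu, oracle$riu)
    expect_identical(got$ua, oracle$ua)
  }
})

test_that("the number of certain records is monotone in the threshold", {
  set.seed(103)
  rec <- tibble::tibble(record_id = sprintf("r%d", 1:30),
                        correct = runif(30) < 0.5, I_norm = runif(30))
  n_cert <- vapply(seq(0, 1, 0.05),
                   function(t) sum(rec$I_norm <= t), numeric(1))
  expect_true(all(diff(n_cert) >= 0))
})

test_that("curve AUCs behave on flat and perfect inputs", {
  rec <- tibble::tibble(record_id = sprintf("r%d", 1:5),
                        correct = TRUE, I_norm = 0)
  tc <- curve_and_auc(rec, n_grid = 51L)
  expect_equal(tc$auc_rcc, 1)
  expect_equal(tc$auc_ua, 1)
  expect_equal(tc$auc_riu, 1)                # vacuous everywhere, flagged
  expect_true(all(tc$curve$riu_vacuous))
})

test_that("toy-set AUCs match a fine-grid Riemann oracle", {
  # refinement check: on a fine grid the trapezoidal AUC converges to the
  # exact integral of the step-valued metrics
  toy <- toy_records()
  tc <- curve_and_auc(toy, n_grid = 2001L)
  fine <- seq(0, 1, length.out = 1e5)
  oracle_auc <- function(metric) {
    vals <- vapply(fine, function(t) {
      oracle_threshold_metrics(toy$correct, toy$I_norm, t)[[metric]]
    }, numeric(1))
    mean(vals)                               # Riemann value on [0, 1]
  }
  expect_equal(tc$auc_rcc, oracle_auc("rcc"), tolerance = 1e-3)
  expect_equal(tc$auc_riu, oracle_auc("riu"), tolerance = 1e-3)
  expect_equal(tc$auc_ua, oracle_auc("ua"), tolerance = 1e-3)
})

test_that("tidy/glance/autoplot expose the threshold curve", {
  tc <- curve_and_auc(toy_records(), n_grid = 21L)
  expect_s3_class(tidy(tc), "tbl_df")
  expect_equal(nrow(tidy(tc)), 21L)
  g <- glance(tc)
  expect_named(g, c("auc_rcc", "auc_riu", "auc_ua", "n_records"))
  expect_s3_class(autoplot(tc), "ggplot")
})

test_that("delta uncertainty reproduces its worked examples", {
  rec_same <- tibble::tibble(record_id = sprintf("r%d", 1:4),
                             correct = c(TRUE, FALSE, TRUE, FALSE),
                             I_norm = 0.4)
  expect_equal(as.numeric(delta_uncertainty(rec_same)), 0)
  rec_sep <- tibble::tibble(record_id = sprintf("r%d", 1:4),
                            correct = c(TRUE, TRUE, FALSE, FALSE),
                            I_norm = c(0, 0, 1, 1))
  expect_equal(as.numeric(delta_uncertainty(rec_sep)), 1)
  d <- delta_uncertainty(toy_records())
  expect_equal(as.numeric(d), (0.2 + 0.8 + 0.6) / 3 - (0.1 + 0.9 + 0.4) / 3,
               tolerance = 1e-12)
  expect_true(is.na(attr(d, "one_sided")))
  # one-sided fallback when a group is absent
  rec_allwrong <- tibble::tibble(record_id = c("a", "b"),
                                 correct = FALSE, I_norm = c(0.5, 0.7))
  d2 <- delta_uncertainty(rec_allwrong)
  expect_equal(as.numeric(d2), 0.6)
  expect_equal(attr(d2, "one_sided"), "incorrect")
})

test_that("mixed datasets honor the requested composition exactly", {
  b <- tiny_batch(25L)                       # N = 100
  id_fn <- function(eps, sub) sub            # attack stub
  spec <- mixed_dataset_spec(c("0" = 0.50, "0.025" = 0.25, "0.05" = 0.15,
                               "0.15" = 0.10), base_seed = 7L)
  mix <- build_mixed_dataset(b, id_fn, spec)
  counts <- table(mix$annotations$epsilon)
  expect_equal(unname(c(counts)), c(50L, 25L, 15L, 10L), ignore_attr = TRUE)
  expect_identical(mix$batch$record_ids, b$record_ids)
  # degenerate all-clean mix returns the input untouched
  mix0 <- build_mixed_dataset(b, id_fn, mixed_dataset_spec(c("0" = 1),
                                                           base_seed = 1L))
  expect_identical(mix0$batch$signals, b$signals)
  expect_error(mixed_dataset_spec(c("0" = 0.6, "1" = 0.5)),
               class = "decorrens_domain_error")
})

test_that("largest-remainder rounding covers awkward sizes", {
  f <- c(0.50, 0.25, 0.15, 0.10)
  expect_equal(decorrens:::largest_remainder(f, 100L), c(50L, 25L, 15L, 10L))
  s7 <- decorrens:::largest_remainder(f, 7L)
  expect_equal(sum(s7), 7L)
  expect_true(all(s7 >= 0))
  # oracle: every stratum within 1 of its exact quota
  expect_true(all(abs(s7 - f * 7) < 1))
  set.seed(104)
  for (rep in 1:20) {
    n <- sample(1:200, 1)
    s <- decorrens:::largest_remainder(f, n)
    expect_equal(sum(s), n)
  }
})

test_that("perturbed strata really get attacked in the mixed build", {
  b <- tiny_batch(10L)
  bump <- function(eps, sub) with_signals(sub, pmin(pmax(
    sub$signals + eps, -1), 1))
  spec <- mixed_dataset_spec(c("0" = 0.5, "0.2" = 0.5), base_seed = 3L)
  mix <- build_mixed_dataset(b, bump, spec)
  touched <- mix$annotations$epsilon > 0
  delta <- apply(abs(mix$batch$signals - b$signals), 1, max)
  expect_true(all(delta[touched] > 0))
  expect_true(all(delta[!touched] == 0))
})

test_that("deferral curve reproduces its worked examples", {
  dc <- deferral_curve(toy_records(), fractions = c(0, 0.5, 1))
  expect_equal(dc$curve$misclassified_pct[1], 0)          # q = 0
  # q = 0.5: the 3 most-confident records (0.1c, 0.2i, 0.4c) -> one wrong
  expect_equal(dc$curve$misclassified_pct[2], 100 / 6, tolerance = 1e-9)
  # perfect ensemble: 0% misclassified at every deferral level
  perfect <- tibble::tibble(record_id = sprintf("r%d", 1:10),
                            correct = TRUE, I_norm = runif(10))
  dp <- deferral_curve(perfect)
  expect_true(all(dp$curve$misclassified_pct == 0))
  expect_equal(dp$auc, 0)
})

test_that("the deferral curve starts at its global minimum", {
  set.seed(105)
  rec <- tibble::tibble(record_id = sprintf("r%d", 1:40),
                        correct = runif(40) < 0.6, I_norm = runif(40))
  dc <- deferral_curve(rec)
  expect_equal(dc$curve$misclassified_pct[1], 0)
  expect_true(all(dc$curve$misclassified_pct >= 0))
  expect_true(all(diff(dc$curve$misclassified_pct) >= 0))  # cumulative errors
  expect_s3_class(tidy(dc), "tbl_df")
  expect_s3_class(autoplot(dc), "ggplot")
})

test_that("deferral ties break deterministically by record id", {
  rec <- tibble::tibble(record_id = c("b", "a", "c"),
                        correct = c(FALSE, TRUE, TRUE),
                        I_norm = c(0.5, 0.5, 0.9))
  d1 <- deferral_curve(rec, fractions = c(0, 1 / 3, 1))
  # "a" (correct) sorts before "b" at equal I_norm
  expect_equal(d1$curve$misclassified_pct[2], 0)
})
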