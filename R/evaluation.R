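#' Certainty-threshold metrics at one threshold
#'
#' A record is *certain* iff `I_norm <= i_t` (out-of-range normalized
#' uncertainties participate as-is). The three measures are
#' \describe{
#'   \item{Rcc}{probability the inference is correct given it is certain;}
#'   \item{Riu}{probability the inference is uncertain given it is
#'     incorrect;}
#'   \item{UA}{probability of the desired outcome: correct-and-certain or
#'     incorrect-and-uncertain.}
#' }
#' Empty denominators (no certain records for Rcc, no incorrect records for
#' Riu) return 1.0 — vacuous truth — and are flagged.
#'
#' @param records Tibble with logical `correct` and numeric `I_norm`
#'   columns (as from [score_batch()]).
#' @param i_t Certainty threshold.
#' @return One-row tibble: `threshold`, `rcc`, `riu`, `ua`, `rcc_vacuous`,
#'   `riu_vacuous`.
#' @export
threshold_metrics <- function(records, i_t) {
  check_that(nrow(records) >= 1, "`records` must be nonempty")
  certain <- records$I_norm <= i_t
  correct <- records$correct
  n <- nrow(records)
  n_cert <- sum(certain)
  n_inc <- sum(!correct)
  n_cc <- sum(correct & certain)
  n_iu <- sum(!correct & !certain)
  tibble::tibble(
    threshold = i_t,
    rcc = if (n_cert == 0L) 1 else n_cc / n_cert,
    riu = if (n_inc == 0L) 1 else n_iu / n_inc,
    ua = (n_cc + n_iu) / n,
    rcc_vacuous = n_cert == 0L,
    riu_vacuous = n_inc == 0L)
}

#' Threshold sweep with areas under the metric curves
#'
#' Evaluates [threshold_metrics()] on an even grid over `[0, 1]` (default
#' 201 points) and integrates each measure over the threshold with the
#' trapezoidal rule. Vacuous values (empty denominators, reported as 1) are
#' included in the integral, which keeps the AUC defined for perfect
#' models.
#'
#' @param records Tibble with `correct` and `I_norm` columns.
#' @param n_grid Number of grid points (>= 2).
#' @return An object of class `threshold_curve`: list with the per-threshold
#'   `curve` tibble and scalars `auc_rcc`, `auc_riu`, `auc_ua`.
#' @export
curve_and_auc <- function(records, n_grid = 201L) {
  check_domain(is_count(n_grid) && n_grid >= 2, "`n_grid` must be >= 2")
  grid <- seq(0, 1, length.out = n_grid)
  curve <- dplyr::bind_rows(lapply(grid, function(t) threshold_metrics(records, t)))
  structure(
    list(curve = curve,
         auc_rcc = trapz(grid, curve$rcc),
         auc_riu = trapz(grid, curve$riu),
         auc_ua = trapz(grid, curve$ua),
         n_records = nrow(records)),
    class = "threshold_curve")
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf(
    "<threshold_curve> %d records, %d thresholds | AUC Rcc %.4f, Riu %.4f, UA %.4f\n",
    x$n_records, nrow(x$curve), x$auc_rcc, x$auc_riu, x$auc_ua))
  invisible(x)
}

#' Mean uncertainty gap between incorrect and correct predictions
#'
#' `E[I_norm | incorrect] - E[I_norm | correct]`. When one side is absent
#' (e.g. an attack that leaves no correct predictions) the one-sided mean of
#' the present group is returned, flagged via the `"one_sided"` attribute
#' (`"incorrect"` or `"correct"`).
#'
#' @param records Tibble with `correct` and `I_norm` columns, nonempty.
#' @return Scalar; attribute `one_sided` is `NA` for the two-sided gap, else
#'   the name of the only group present.
#' @export
delta_uncertainty <- function(records) {
  check_that(nrow(records) >= 1, "`records` must be nonempty")
  inc <- records$I_norm[!records$correct]
  cor <- records$I_norm[records$correct]
  if (length(inc) > 0 && length(cor) > 0) {
    out <- mean(inc) - mean(cor)
    attr(out, "one_sided") <- NA_character_
  } else if (length(inc) > 0) {
    out <- mean(inc)
    attr(out, "one_sided") <- "incorrect"
  } else {
    out <- mean(cor)
    attr(out, "one_sided") <- "correct"
  }
  out
}

#' Specification of a partially attacked (mixed) dataset
#'
#' @param fractions Named numeric vector mapping attack magnitude (as a
#'   character or numeric name, `"0"` meaning unperturbed) to the fraction
#'   of records receiving it; must sum to 1. The default is the 50% clean /
#'   25% / 15% / 10% composition used for deferral analysis.
#' @param base_seed Integer seed for the record-to-stratum assignment.
#' @return An object of class `mixed_dataset_spec`.
#' @export
mixed_dataset_spec <- function(fractions = c("0" = 0.50, "0.025" = 0.25,
                                             "0.05" = 0.15, "0.15" = 0.10),
                               base_seed = 1L) {
  check_domain(abs(sum(fractions) - 1) <= 1e-9, "`fractions` must sum to 1")
  check_domain(all(fractions >= 0), "`fractions` must be nonnegative")
  check_domain(!is.null(names(fractions)), "`fractions` must be named by epsilon")
  structure(list(fractions = fractions, base_seed = as.integer(base_seed)),
            class = "mixed_dataset_spec")
}

# Largest-remainder apportionment of n records to the given fractions.
largest_remainder <- function(fractions, n) {
  quota <- fractions * n
  base <- floor(quota + 1e-9)
  left <- n - sum(base)
  if (left > 0) {
    rem <- quota - base
    extra <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Build a partially attacked dataset
#'
#' Records are assigned to perturbation strata by a seeded random
#' permutation, with stratum sizes fixed by largest-remainder rounding of
#' the requested fractions. Each nonzero stratum is replaced by
#' `attack_fn(epsilon, subbatch)`; the zero stratum stays untouched. The
#' output keeps the original record order.
#'
#' @param clean A labeled [signal_batch()].
#' @param attack_fn Function `(epsilon, batch) -> signal_batch` producing
#'   the perturbed copy of a sub-batch.
#' @param spec A [mixed_dataset_spec()].
#' @return List with `batch` (the mixed [signal_batch()]) and `annotations`
#'   (tibble `record_id`, `epsilon`).
#' @export
build_mixed_dataset <- function(clean, attack_fn, spec) {
  check_that(inherits(spec, "mixed_dataset_spec"),
             "`spec` must be a mixed_dataset_spec")
  n <- n_records(clean)
  eps_values <- as.numeric(names(spec$fractions))
  sizes <- largest_remainder(spec$fractions, n)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(spec$base_seed, 31L))
  perm <- sample.int(n)

  signals <- clean$signals
  eps_of <- numeric(n)
  offset <- 0L
  for (j in seq_along(eps_values)) {
    if (sizes[j] == 0L) next
    idx <- perm[(offset + 1L):(offset + sizes[j])]
    offset <- offset + sizes[j]
    eps_of[idx] <- eps_values[j]
    if (eps_values[j] > 0) {
      sub <- subset_batch(clean, idx)
      pb <- attack_fn(eps_values[j], sub)
      signals[idx, , ] <- pb$signals
    }
  }
  out <- with_signals(clean, signals)
  list(batch = out,
       annotations = tibble::tibble(record_id = clean$record_ids,
                                    epsilon = eps_of))
}

#' Deferral (clinician-triage) curve
#'
#' Records are ordered from most to least confident (ascending normalized
#' uncertainty; ties broken by record id for determinism). For each
#' deferral fraction `q`, the `floor(q * N)` most-confident records take
#' the ensemble's answer while all remaining records are assumed correctly
#' handled by human reviewers; the curve reports the percentage of the
#' whole dataset that ends up misclassified, with its trapezoidal AUC
#' (lower is better).
#'
#' @param records Tibble with `record_id`, `correct`, `I_norm` columns.
#' @param fractions Grid of deferral fractions over `[0, 1]` (default 201
#'   even points).
#' @return An object of class `deferral_curve`: list with the `curve`
#'   tibble (`fraction`, `misclassified_pct`) and scalar `auc`.
#' @export
deferral_curve <- function(records, fractions = seq(0, 1, length.out = 201L)) {
  check_that(nrow(records) >= 1, "`records` must be nonempty")
  ord <- order(records$I_norm, records$record_id)
  wrong_cum <- c(0, cumsum(!records$correct[ord]))
  n <- nrow(records)
  k <- pmin(n, floor(fractions * n + 1e-9))
  pct <- 100 * wrong_cum[k + 1L] / n
  structure(
    list(curve = tibble::tibble(fraction = fractions, misclassified_pct = pct),
         auc = trapz(fractions, pct),
         n_records = n),
    class = "deferral_curve")
}

#' @export
print.deferral_curve <- function(x, ...) {
  cat(sprintf("<deferral_curve> %d records | AUC %.3f%% (lower is better)\n",
              x$n_records, x$auc))
  invisible(x)
}
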