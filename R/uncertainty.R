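#' Mutual-information uncertainty of one ensemble inference
#'
#' For `K` member probability rows over `C` classes, the epistemic
#' uncertainty is the mutual information between the predicted label and
#' the model parameters, estimated as the entropy of the mean member
#' distribution minus the mean of member entropies (natural log,
#' `0 * log 0 := 0`):
#' `I = H(mean_k p_k) - mean_k H(p_k)`.
#' `I` is zero when all members agree exactly and at most `log C`.
#'
#' @param member_probs `K x C` matrix; each row a probability vector
#'   (checked to sum to 1 within `1e-4`).
#' @return Scalar uncertainty in nats (>= 0).
#' @export
mutual_information <- function(member_probs) {
  member_probs <- as.matrix(member_probs)
  check_that(all(member_probs >= -1e-12),
             "member probabilities must be nonnegative")
  check_that(all(abs(rowSums(member_probs) - 1) <= 1e-4),
             "member probability rows must sum to 1")
  mean_p <- colMeans(member_probs)
  i <- -sum(xlogx(mean_p)) + mean(rowSums(xlogx(member_probs)))
  check_that(i >= -1e-9, "internal error: negative mutual information")
  max(i, 0)
}

# Per-record mutual information for a whole batch from the (K, N, C) member
# probability array.
batch_mutual_information <- function(mp) {
  k <- dim(mp)[1L]; n <- dim(mp)[2L]
  mean_p <- colMeans(mp)                      # (N, C)
  h_mean <- -rowSums(xlogx(mean_p))
  h_members <- matrix(0, k, n)
  for (j in seq_len(k)) h_members[j, ] <- -rowSums(xlogx(mp[j, , ]))
  i <- h_mean - colMeans(h_members)
  pmax(i, 0)
}

#' Calibrate uncertainty normalization bounds on the training set
#'
#' Computes the minimum and maximum mutual-information uncertainty over all
#' training records (post hoc, with the final weights), which anchor the
#' normalized uncertainty scale. An ensemble whose members agree everywhere
#' (e.g. identical members) has no spread to normalize and raises a
#' degeneracy error.
#'
#' @param ensemble A trained `ecg_ensemble`.
#' @param training_batch The [signal_batch()] the ensemble was trained on.
#' @return An object of class `calibration_bounds` with fields `i_min`,
#'   `i_max`, `source`.
#' @export
calibrate_bounds <- function(ensemble, training_batch) {
  i_vals <- batch_mutual_information(member_probs(ensemble, training_batch))
  i_min <- min(i_vals); i_max <- max(i_vals)
  if (i_max - i_min <= 1e-12) {
    rlang::abort(sprintf(
      "degenerate uncertainty bounds (I_min = I_max = %.3g): ensemble members do not disagree on any training record",
      i_max), class = "decorrens_domain_error")
  }
  structure(list(i_min = i_min, i_max = i_max,
                 source = rlang::hash(training_batch$record_ids)),
            class = "calibration_bounds")
}

#' Normalize raw uncertainty by the training-set bounds
#'
#' The affine rescale `(I - I_min) / (I_max - I_min)`. Test records can be
#' more or less uncertain than anything seen during training, so the result
#' is deliberately *not* clamped to `[0, 1]`.
#'
#' @param i Raw mutual information (vectorized), nats.
#' @param bounds A `calibration_bounds`.
#' @return Normalized uncertainty, same length as `i`.
#' @export
normalize_uncertainty <- function(i, bounds) {
  check_that(inherits(bounds, "calibration_bounds"), "`bounds` must come from calibrate_bounds()")
  (i - bounds$i_min) / (bounds$i_max - bounds$i_min)
}

#' Score a batch: ensemble predictions with per-record uncertainty
#'
#' For every record: the ensemble-average prediction, its probability (max
#' of the mean distribution), the raw mutual-information uncertainty, its
#' normalized value, and correctness against the batch label.
#'
#' @param ensemble A trained `ecg_ensemble`.
#' @param batch A labeled [signal_batch()].
#' @param bounds A `calibration_bounds` from [calibrate_bounds()].
#' @return A tibble with columns `record_id`, `label`, `predicted_class`,
#'   `predicted_prob`, `raw_I`, `I_norm`, `correct`, ordered as the batch.
#' @export
score_batch <- function(ensemble, batch, bounds) {
  mp <- member_probs(ensemble, batch)
  mean_p <- colMeans(mp)
  pred <- max.col(mean_p, ties.method = "first") - 1L
  raw_i <- batch_mutual_information(mp)
  tibble::tibble(
    record_id = batch$record_ids,
    label = batch$labels,
    predicted_class = pred,
    predicted_prob = mean_p[cbind(seq_len(nrow(mean_p)), pred + 1L)],
    raw_I = raw_i,
    I_norm = normalize_uncertainty(raw_i, bounds),
    correct = pred == batch$labels)
}

#' Write / read scored batches as CSV
#'
#' @param scores A tibble from [score_batch()].
#' @param path CSV path.
#' @return `write_scores` returns `path` invisibly; `read_scores` the
#'   tibble.
#' @export
write_scores <- function(scores, path) {
  readr::write_csv(scores, path)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    record_id = readr::col_character(),
                    label = readr::col_integer(),
                    predicted_class = readr::col_integer(),
                    correct = readr::col_logical()))
}
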