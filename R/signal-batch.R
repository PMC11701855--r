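#' Construct a batch of fixed-length multi-channel signals
#'
#' A signal batch is the basic data container of the package: an
#' `N x channels x T` numeric array with amplitudes in `[-1, 1]`, one integer
#' class label per record (zero-based, `0 .. C-1`), and a unique character id
#' per record. Record ids key the feature caches used by decorrelation
#' training, so they must be unique.
#'
#' @param signals Numeric array of dimension `N x channels x T`, values in
#'   `[-1, 1]`.
#' @param labels Integer vector of length `N`, values in `0 .. n_classes - 1`.
#' @param record_ids Character vector of length `N`, unique.
#' @param sampling_rate Sampling rate in Hz.
#' @param n_classes Number of classes `C`; defaults to `max(labels) + 1`.
#' @param class_names Optional character vector of length `n_classes`.
#'
#' @return An object of class `signal_batch`: a list with elements `signals`,
#'   `labels`, `record_ids`, `sampling_rate`, `n_classes`, `class_names`.
#' @export
signal_batch <- function(signals, labels, record_ids, sampling_rate,
                         n_classes = NULL, class_names = NULL) {
  check_that(is.array(signals) && length(dim(signals)) == 3L,
             "`signals` must be an N x channels x T array")
  n <- dim(signals)[1L]
  check_that(length(labels) == n, "`labels` length must match N")
  check_that(length(record_ids) == n, "`record_ids` length must match N")
  check_that(!anyDuplicated(record_ids), "`record_ids` must be unique")
  check_that(all(is.finite(signals)), "`signals` must be finite")
  check_that(max(abs(signals)) <= 1 + 1e-12,
             "`signals` amplitudes must lie in [-1, 1]")
  labels <- as.integer(labels)
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  check_that(all(labels >= 0L & labels < n_classes),
             "`labels` must lie in [0, n_classes)")
  structure(
    list(signals = signals, labels = labels,
         record_ids = as.character(record_ids),
         sampling_rate = sampling_rate,
         n_classes = as.integer(n_classes),
         class_names = class_names),
    class = "signal_batch")
}

#' @export
print.signal_batch <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf("<signal_batch> %d records, %d channel(s), %d samples @ %g Hz, %d classes\n",
              d[1L], d[2L], d[3L], x$sampling_rate, x$n_classes))
  invisible(x)
}

#' Number of records in a signal batch
#' @param batch A `signal_batch`.
#' @return Integer record count.
#' @export
n_records <- function(batch) dim(batch$signals)[1L]

#' Subset a signal batch by record index
#'
#' @param batch A `signal_batch`.
#' @param idx Integer (1-based) record indices.
#' @return A `signal_batch` with the selected records, in the given order.
#' @export
subset_batch <- function(batch, idx) {
  check_that(all(idx >= 1 & idx <= n_records(batch)), "record index out of range")
  signal_batch(batch$signals[idx, , , drop = FALSE], batch$labels[idx],
               batch$record_ids[idx], batch$sampling_rate,
               n_classes = batch$n_classes, class_names = batch$class_names)
}

#' Replace the signal array of a batch, keeping labels and ids
#'
#' Used by attacks and filters, which modify signals but not metadata.
#' Amplitudes may leave `[-1, 1]` after perturbation only when the caller
#' allows it via `clip = FALSE` validation bypass; by default values are
#' validated.
#'
#' @param batch A `signal_batch`.
#' @param signals Replacement `N x channels x T` array.
#' @param validate_amplitude If `FALSE`, skip the `[-1, 1]` amplitude check
#'   (filtered or perturbed signals can legitimately exceed it slightly).
#' @return A `signal_batch`.
#' @export
with_signals <- function(batch, signals, validate_amplitude = FALSE) {
  check_that(identical(dim(signals), dim(batch$signals)),
             "replacement signals must keep the batch dimensions")
  out <- batch
  if (validate_amplitude) {
    check_that(max(abs(signals)) <= 1 + 1e-12, "amplitudes must lie in [-1, 1]")
  }
  out$signals <- signals
  out
}

#' Split a batch into training and held-out parts
#'
#' The split is a seeded random partition, stratified nowhere: with shuffled
#' balanced batches the class mix of both parts is close to balanced.
#'
#' @param batch A `signal_batch`.
#' @param frac_train Fraction of records assigned to the training part.
#' @param seed Integer seed for the partition.
#' @return A list with elements `train` and `test`, both `signal_batch`.
#' @export
split_batch <- function(batch, frac_train = 0.9, seed = 1L) {
  check_domain(frac_train > 0 && frac_train < 1, "`frac_train` must be in (0, 1)")
  n <- n_records(batch)
  n_train <- max(1L, min(n - 1L, round(frac_train * n)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 17L))
  idx <- sample.int(n)
  list(train = subset_batch(batch, sort(idx[seq_len(n_train)])),
       test  = subset_batch(batch, sort(idx[(n_train + 1L):n])))
}

# Save/restore of the global RNG state so seeded helpers do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write / read a signal batch on disk
#'
#' The array container is R's serialization format (one file holding
#' `signals`, `labels`, `record_ids`, `sampling_rate`, class metadata);
#' a plain-text CSV label manifest (`record_id,label`) is written next to it
#' for interoperability.
#'
#' @param batch A `signal_batch`.
#' @param path Output path for the array container (e.g. `batch.rds`).
#' @return `write_signal_batch` returns `path` invisibly; `read_signal_batch`
#'   returns a `signal_batch`.
#' @export
write_signal_batch <- function(batch, path) {
  saveRDS(unclass(batch), path)
  manifest <- data.frame(record_id = batch$record_ids, label = batch$labels)
  utils::write.csv(manifest, paste0(path, ".labels.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_batch
#' @export
read_signal_batch <- function(path) {
  x <- readRDS(path)
  signal_batch(x$signals, x$labels, x$record_ids, x$sampling_rate,
               n_classes = x$n_classes, class_names = x$class_names)
}

#' Pad or truncate signals to a fixed length, then rescale to `[-1, 1]`
#'
#' Mirrors the preprocessing applied to the real challenge recordings:
#' zero-padding (or truncation) to a fixed duration happens first, then each
#' record is max-abs normalized so every channel lies in `[-1, 1]`. A
#' pluggable `scale_fn` hook replaces the default max-abs scaling when a
#' dataset-specific amplitude recipe is required.
#'
#' @param signals `N x channels x T0` array.
#' @param target_length Desired number of samples `T`.
#' @param scale_fn Function mapping an `N x channels x T` array to a rescaled
#'   array in `[-1, 1]`; default is per-record max-abs scaling.
#' @return `N x channels x target_length` array in `[-1, 1]`.
#' @export
pad_truncate_normalize <- function(signals, target_length,
                                   scale_fn = maxabs_scale) {
  d <- dim(signals)
  check_domain(is_count(target_length), "`target_length` must be a positive count")
  out <- array(0, c(d[1L], d[2L], target_length))
  keep <- min(d[3L], target_length)
  out[, , seq_len(keep)] <- signals[, , seq_len(keep)]
  scale_fn(out)
}

#' @rdname pad_truncate_normalize
#' @param x `N x channels x T` array.
#' @export
maxabs_scale <- function(x) {
  n <- dim(x)[1L]
  for (i in seq_len(n)) {
    m <- max(abs(x[i, , ]))
    if (m > 0) x[i, , ] <- x[i, , ] / m
  }
  x
}
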