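#' Construct a classifier ensemble
#'
#' An ensemble is an ordered list of `K >= 1` classifiers sharing a class
#' count, plus one optional input transform per member (identity by
#' default). Member order is training order: member 1 of the list is
#' "model 0", the first model trained and the default single-model attack
#' target.
#'
#' @param members List of classifiers (each `ecg_classifier` or
#'   `linear_softmax`).
#' @param input_transforms `NULL` (all identity) or a list of length `K`
#'   whose entries are `NULL` or `band_transform` objects.
#' @return An object of class `ecg_ensemble`.
#' @export
new_ensemble <- function(members, input_transforms = NULL) {
  check_that(is.list(members) && length(members) >= 1,
             "`members` must be a nonempty list of classifiers")
  ncls <- vapply(members, function(m) as.integer(m$spec$n_classes %||% m$n_classes),
                 integer(1))
  check_that(length(unique(ncls)) == 1L, "all members must share n_classes")
  k <- length(members)
  if (is.null(input_transforms)) {
    input_transforms <- vector("list", k)
  }
  check_that(length(input_transforms) == k,
             "`input_transforms` must have one entry per member")
  structure(list(members = members, input_transforms = input_transforms,
                 n_classes = ncls[1L]),
            class = "ecg_ensemble")
}

#' @export
print.ecg_ensemble <- function(x, ...) {
  n_filt <- sum(!vapply(x$input_transforms, is.null, logical(1)))
  cat(sprintf("<ecg_ensemble> K=%d member(s), C=%d%s\n",
              length(x$members), x$n_classes,
              if (n_filt) sprintf(", %d filtered input(s)", n_filt) else ""))
  invisible(x)
}

#' Number of ensemble members
#' @param ensemble An `ecg_ensemble`.
#' @return Integer `K`.
#' @export
n_members <- function(ensemble) length(ensemble$members)

# Input as seen by member k (1-based list index) after its transform.
member_input <- function(ensemble, k, x) {
  apply_transform(ensemble$input_transforms[[k]], x)
}

#' Per-member class probabilities
#'
#' @param ensemble An `ecg_ensemble`.
#' @param batch A [signal_batch()] or `N x channels x T` array.
#' @return A `K x N x C` array of member probabilities (member transforms
#'   applied).
#' @export
member_probs <- function(ensemble, batch) {
  x <- batch_signals(batch)
  k <- n_members(ensemble)
  p1 <- predict_member(ensemble$members[[1L]], member_input(ensemble, 1L, x))
  out <- array(0, c(k, nrow(p1), ncol(p1)))
  out[1L, , ] <- p1
  if (k > 1L) {
    for (j in 2:k) {
      out[j, , ] <- predict_member(ensemble$members[[j]],
                                   member_input(ensemble, j, x))
    }
  }
  out
}

#' Ensemble-average class probabilities
#'
#' The ensemble inference is the arithmetic mean of the member probability
#' outputs, each member seeing its own (possibly band-filtered) input.
#'
#' @param ensemble An `ecg_ensemble`.
#' @param batch A [signal_batch()] or `N x channels x T` array.
#' @return `N x C` matrix of averaged probabilities; rows sum to 1.
#' @export
predict_ensemble <- function(ensemble, batch) {
  mp <- member_probs(ensemble, batch)
  colMeans(mp)                              # mean over the member dimension
}

#' Classification accuracy of an ensemble on a labeled batch
#'
#' @param ensemble An `ecg_ensemble`.
#' @param batch A labeled [signal_batch()].
#' @return Fraction of records whose argmax ensemble prediction matches the
#'   label.
#' @export
ensemble_accuracy <- function(ensemble, batch) {
  p <- predict_ensemble(ensemble, batch)
  pred <- max.col(p, ties.method = "first") - 1L
  mean(pred == batch$labels)
}
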