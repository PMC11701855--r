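#' Decorrelation hyperparameters
#'
#' Controls the regression-based feature-decorrelation loss: the loss weight
#' `lambda_weight` balancing cross-entropy against decorrelation, the random
#' projection width `projection_dim` (`r`), and the stability constant
#' `stability_eps` added inside both logarithms of the loss.
#'
#' @param lambda_weight Nonnegative loss weight (default 0.2).
#' @param projection_dim Projection width `r`; must satisfy `r < D + 1`
#'   (default 32 for the default feature width `D = 64`).
#' @param stability_eps Positive stability constant (default `1e-5`).
#' @param seed Optional integer seed recorded for bookkeeping; the projection
#'   and swap draws use the training loop's random stream.
#' @return An object of class `decorr_config`.
#' @export
decorr_config <- function(lambda_weight = 0.2, projection_dim = 32L,
                          stability_eps = 1e-5, seed = NULL) {
  check_domain(is_scalar_num(lambda_weight) && lambda_weight >= 0,
               "`lambda_weight` must be >= 0")
  check_domain(is_count(projection_dim), "`projection_dim` must be a positive count")
  check_domain(is_scalar_num(stability_eps) && stability_eps > 0,
               "`stability_eps` must be > 0")
  structure(list(lambda_weight = lambda_weight,
                 projection_dim = as.integer(projection_dim),
                 stability_eps = stability_eps, seed = seed),
            class = "decorr_config")
}

# Core least-squares machinery: regress Z2 on [X1, 1] via a QR solve (never
# an explicit inverse); rank-deficient regressors fall back to the pivoted
# minimum-norm solution without error. Returns the loss value and, on
# request, analytic gradients with respect to both arguments (envelope
# theorem: at the least-squares optimum, dSSres/dX = -2 * residual %*% t(beta)).
lr_loss_impl <- function(x1, z2, eps, want_grads = FALSE) {
  n <- nrow(z2)
  x <- cbind(x1, 1)
  qr_x <- qr(x)
  res <- qr.resid(qr_x, z2)
  ssres <- sum(res * res)
  z2c <- z2 - rep(colMeans(z2), each = n)
  sstot <- sum(z2c * z2c)
  val <- log(sstot + eps) - log(ssres + eps)
  out <- list(value = val, ssres = ssres, sstot = sstot)
  if (want_grads) {
    beta <- qr.coef(qr_x, z2)
    beta[is.na(beta)] <- 0
    g_x <- (2 / (ssres + eps)) * tcrossprod(res, beta)
    out$grad_x1 <- g_x[, seq_len(ncol(x1)), drop = FALSE]
    out$grad_z2 <- 2 * (z2c / (sstot + eps) - res / (ssres + eps))
  }
  out
}

#' Regression-based decorrelation loss between two feature matrices
#'
#' Measures the linear predictability of `z2` from `z1` as
#' `log(SStot + eps) - log(SSres + eps)`, where `SSres` is the residual sum
#' of squares of the ordinary least-squares fit of `z2` on `[z1, 1]` and
#' `SStot = ||z2 - mean(z2)||^2` uses column-wise means. With `eps = 0` and
#' nondegenerate inputs, `exp(-lr_loss) = SSres / SStot = 1 - R^2`, so the
#' loss grows as `z2` becomes more linearly predictable from `z1`.
#'
#' @param z1 Regressor feature matrix `N x D1` (the intercept column is
#'   appended internally).
#' @param z2 Regressand feature matrix `N x D2`.
#' @param eps Stability constant added inside both logarithms.
#' @return Scalar loss value (>= 0 up to the epsilon regularization).
#' @export
lr_loss <- function(z1, z2, eps = 1e-5) {
  z1 <- as.matrix(z1); z2 <- as.matrix(z2)
  check_that(nrow(z1) == nrow(z2), "`z1` and `z2` must have the same N")
  check_that(nrow(z1) >= 2, "need at least two rows")
  check_that(all(is.finite(z1)) && all(is.finite(z2)),
             "feature matrices must be finite")
  lr_loss_impl(z1, z2, eps)$value
}

# Internal randomized loss with gradient w.r.t. `zk` (the model currently
# being trained). Draws the swap coin and projection from the current RNG:
# one fresh coin and one fresh R per call, matching the per-prior-model
# placement of the draws in the training step.
randomized_lr_loss_impl <- function(zk, zi, config, want_grads = FALSE) {
  d <- ncol(zk)
  r <- config$projection_dim
  check_that(ncol(zi) == d, "feature matrices must share D")
  check_that(nrow(zk) == nrow(zi), "feature matrices must share N")
  check_that(r < d + 1, "`projection_dim` must satisfy r < D + 1")
  swap <- runif(1) < 0.5
  z1 <- zk; z2 <- zi
  if (swap) { z1 <- zi; z2 <- zk }
  proj <- matrix(rnorm((d + 1L) * r, sd = sqrt(1 / d)), d + 1L, r)
  x1p <- cbind(z1, 1) %*% proj
  impl <- lr_loss_impl(x1p, z2, config$stability_eps, want_grads = want_grads)
  out <- list(value = impl$value, swapped = swap, projection = proj)
  if (want_grads) {
    out$grad_zk <- if (swap) {
      impl$grad_z2
    } else {
      (impl$grad_x1 %*% t(proj))[, seq_len(d), drop = FALSE]
    }
  }
  out
}

#' Randomized-projection decorrelation loss
#'
#' The scalable variant of [lr_loss()] used during ensemble training: with
#' probability 1/2 the roles of the two feature matrices are swapped, the
#' regressor gets an intercept column appended and is compressed from `D + 1`
#' to `r` dimensions by a random projection with i.i.d. `N(0, 1/D)` entries,
#' and [lr_loss()] is evaluated on the compressed regressor. A fresh
#' projection and coin are drawn from the current random stream on every
#' call, so repeated calls decorrelate different random subspaces.
#'
#' @param zk Feature matrix of the model being trained (`N x D`).
#' @param zi Feature matrix of a previously trained model (`N x D`).
#' @param config A [decorr_config()].
#' @return Scalar loss value.
#' @export
randomized_lr_loss <- function(zk, zi, config = decorr_config()) {
  randomized_lr_loss_impl(as.matrix(zk), as.matrix(zi), config)$value
}

#' Total training loss with decorrelation
#'
#' Combines a cross-entropy value with the decorrelation penalty against all
#' previously trained models:
#' `ce + lambda * mean_i randomized_lr_loss(zk, cached[[i]])`. With no prior
#' models (`length(cached) == 0`) the cross-entropy is returned unchanged.
#'
#' @param ce_loss Scalar cross-entropy value.
#' @param zk Feature matrix of the model being trained; may carry a
#'   `record_ids` attribute.
#' @param cached List of prior models' feature matrices aligned row-by-row
#'   with `zk` (checked via `record_ids` attributes when present).
#' @param config A [decorr_config()].
#' @return Scalar total loss.
#' @export
decorr_total_loss <- function(ce_loss, zk, cached = list(),
                              config = decorr_config()) {
  k <- length(cached)
  if (k == 0L || config$lambda_weight == 0) return(ce_loss)
  ids <- attr(zk, "record_ids")
  total <- 0
  for (zi in cached) {
    ids_i <- attr(zi, "record_ids")
    if (!is.null(ids) && !is.null(ids_i)) {
      check_that(identical(ids, ids_i),
                 "record_ids of cached features are misaligned with `zk`")
    }
    total <- total + randomized_lr_loss(zk, zi, config)
  }
  ce_loss + config$lambda_weight * total / k
}

# ---- Feature caches --------------------------------------------------------

#' Cache a trained model's features over a dataset
#'
#' After a model finishes training, its penultimate features on every
#' training record are extracted once (evaluation mode) and stored keyed by
#' record id, so later models can decorrelate against them as constants
#' without keeping earlier models in memory. The cache is stored sorted by
#' record id, making it independent of the batch order used to build it.
#'
#' @param model A trained `ecg_classifier`.
#' @param batch The [signal_batch()] of training records.
#' @param transform Optional per-member input filter (a `band_transform`)
#'   applied before feature extraction, as during that member's training.
#' @param model_index Optional integer bookkeeping index `k`.
#' @return An object of class `feature_cache`.
#' @export
build_feature_cache <- function(model, batch, transform = NULL,
                                model_index = NULL) {
  x <- batch$signals
  if (!is.null(transform)) x <- apply_transform(transform, x)
  z <- extract_features(model, x)
  ids <- batch$record_ids
  ord <- order(ids)
  structure(
    list(record_ids = ids[ord], values = z[ord, , drop = FALSE],
         model_index = model_index, feature_dim = ncol(z),
         dataset_hash = rlang::hash(ids[ord])),
    class = "feature_cache")
}

#' Look up cached feature rows for a set of records
#'
#' @param cache A `feature_cache`.
#' @param ids Character record ids; all must be present in the cache.
#' @return `length(ids) x D` matrix in the order of `ids`, with a
#'   `record_ids` attribute.
#' @export
cache_rows <- function(cache, ids) {
  idx <- match(ids, cache$record_ids)
  check_that(!anyNA(idx), "records missing from feature cache")
  out <- cache$values[idx, , drop = FALSE]
  attr(out, "record_ids") <- ids
  out
}

#' Persist / reload a feature cache
#'
#' The array container round-trips bit-exactly; a JSON manifest (model
#' index, feature dimension, record count, dataset hash) is written next to
#' it for inspection.
#'
#' @param cache A `feature_cache`.
#' @param path Output path (e.g. `cache_model0.rds`).
#' @return `write_feature_cache` returns `path` invisibly;
#'   `read_feature_cache` returns the `feature_cache`.
#' @export
write_feature_cache <- function(cache, path) {
  saveRDS(unclass(cache), path)
  manifest <- list(model_index = cache$model_index,
                   feature_dim = cache$feature_dim,
                   n_records = length(cache$record_ids),
                   dataset_hash = cache$dataset_hash)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_feature_cache
#' @export
read_feature_cache <- function(path) {
  x <- readRDS(path)
  structure(x, class = "feature_cache")
}
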