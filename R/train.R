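#' Training hyperparameters
#'
#' @param epochs Number of passes over the training data.
#' @param batch_size Mini-batch size (default 64).
#' @param learning_rate Optimizer step size (default `1e-3`).
#' @param optimizer_name Currently only `"adam"`.
#' @param seed Integer seed controlling batch shuffling and all random draws
#'   made during training (decorrelation coins and projections included).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs, batch_size = 64L, learning_rate = 1e-3,
                         optimizer_name = "adam", seed = 1L) {
  check_domain(is_count(epochs), "`epochs` must be a positive count")
  check_domain(is_count(batch_size), "`batch_size` must be a positive count")
  check_domain(is_scalar_num(learning_rate) && learning_rate >= 0,
               "`learning_rate` must be >= 0")
  check_domain(identical(optimizer_name, "adam"),
               "only the \"adam\" optimizer is implemented")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer_name = optimizer_name,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' One decorrelated (or plain) training step
#'
#' Computes the model's penultimate features and class predictions on one
#' mini-batch, the cross-entropy loss, and — when prior-model features are
#' supplied — the randomized decorrelation losses against each prior model
#' (fresh swap coin and projection per prior model, drawn from the current
#' random stream), each weighted by `lambda / k`. The combined gradient is
#' backpropagated and one Adam step is applied. With no prior features (or
#' `lambda = 0`) the update is exactly a plain cross-entropy step.
#'
#' When the mini-batch is smaller than `projection_dim + 1` the regression
#' is underdetermined and the decorrelation term is skipped for that batch
#' (reported via `skipped`).
#'
#' @param model An `ecg_classifier`.
#' @param signals `N x channels x T` array for the mini-batch.
#' @param labels Zero-based integer labels for the mini-batch.
#' @param prior_features List of `N x D` matrices: the prior models'
#'   features for exactly these records, in batch order.
#' @param decorr A [decorr_config()] (ignored when `prior_features` is empty).
#' @param opt_state Adam state from [adam_init] on the model's parameters.
#' @param learning_rate Step size.
#' @return List with `model`, `opt_state`, `ce` and `corr` loss components,
#'   `features` (the batch feature matrix `Z_k`), and `skipped`.
#' @export
decorrelated_training_step <- function(model, signals, labels,
                                       prior_features = list(),
                                       decorr = decorr_config(),
                                       opt_state, learning_rate) {
  fwd <- nn_forward(model, signals, training = TRUE)
  model$state <- fwd$model_state
  cg <- ce_loss_grad(fwd$logits, fwd$probs, labels)

  k <- length(prior_features)
  corr <- 0
  dfeat <- NULL
  skipped <- FALSE
  if (k > 0L && decorr$lambda_weight > 0) {
    if (nrow(fwd$features) < decorr$projection_dim + 1L) {
      skipped <- TRUE
    } else {
      w <- decorr$lambda_weight / k
      for (zi in prior_features) {
        rl <- randomized_lr_loss_impl(fwd$features, zi, decorr,
                                      want_grads = TRUE)
        corr <- corr + w * rl$value
        dfeat <- if (is.null(dfeat)) w * rl$grad_zk else dfeat + w * rl$grad_zk
      }
    }
  }
  if (!is.finite(cg$loss) || !is.finite(corr)) {
    rlang::abort(sprintf(
      "non-finite loss during training step (ce=%g, corr=%g)", cg$loss, corr),
      class = "decorrens_numeric_error")
  }
  bwd <- nn_backward(model, fwd$cache, dlogits = cg$dlogits,
                     dfeat_extra = dfeat)
  upd <- adam_step(model$params, bwd$grads, opt_state, learning_rate)
  model$params <- upd$params
  list(model = model, opt_state = upd$state, ce = cg$loss, corr = corr,
       features = fwd$features, skipped = skipped)
}

# Shared training loop for plain, decorrelated and band-filtered members.
train_member <- function(model, batch, config, decorr = NULL,
                         prior_caches = list(), transform = NULL) {
  signals <- batch$signals
  if (!is.null(transform)) signals <- apply_transform(transform, signals)
  labels <- batch$labels
  ids <- batch$record_ids
  n <- length(labels)
  if (is.null(decorr)) decorr <- decorr_config()

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 211L))

  opt <- adam_init(model$params)
  trace <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ce_sum <- 0; corr_sum <- 0; nb <- 0L; n_skipped <- 0L
    for (start in seq.int(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- signals[idx, , , drop = FALSE]
      yb <- labels[idx]
      rows <- lapply(prior_caches, cache_rows, ids = ids[idx])
      step <- decorrelated_training_step(model, xb, yb, rows, decorr, opt,
                                         config$learning_rate)
      model <- step$model
      opt <- step$opt_state
      ce_sum <- ce_sum + step$ce
      corr_sum <- corr_sum + step$corr
      nb <- nb + 1L
      if (step$skipped) n_skipped <- n_skipped + 1L
    }
    trace[[ep]] <- tibble::tibble(epoch = ep, ce = ce_sum / nb,
                                  corr = corr_sum / nb,
                                  skipped_batches = n_skipped)
  }
  list(model = model, trace = dplyr::bind_rows(trace))
}

#' Train a classifier with plain cross-entropy
#'
#' Minimizes cross-entropy with Adam over seeded shuffled mini-batches and
#' records a per-epoch loss trace. Seeded runs are reproducible on one
#' device. A non-finite loss aborts with a diagnostic.
#'
#' @param model An initialized `ecg_classifier`.
#' @param batch Labeled training [signal_batch()].
#' @param config A [train_config()].
#' @param transform Optional `band_transform` applied to all inputs (the
#'   member's partition filter).
#' @return List with the trained `model` and a tibble `trace` of per-epoch
#'   mean losses.
#' @export
train_plain <- function(model, batch, config, transform = NULL) {
  train_member(model, batch, config, transform = transform)
}

#' Train a classifier with decorrelation against cached prior models
#'
#' The model minimizes cross-entropy plus the `lambda`-weighted average of
#' randomized decorrelation losses against each prior model's cached
#' features (constants; gradients flow only through the current model's
#' features).
#'
#' @inheritParams train_plain
#' @param decorr A [decorr_config()].
#' @param prior_caches List of `feature_cache` objects for models
#'   `0 .. k-1`, covering every training record.
#' @return List with the trained `model` and the per-epoch `trace`
#'   (cross-entropy and decorrelation components).
#' @export
train_decorrelated <- function(model, batch, config, decorr = decorr_config(),
                               prior_caches = list(), transform = NULL) {
  train_member(model, batch, config, decorr = decorr,
               prior_caches = prior_caches, transform = transform)
}
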