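#' Specification of the compact 1D convolutional classifier
#'
#' Defines a small, fully configurable 1D CNN for fixed-length multi-channel
#' signals: `length(conv_widths)` blocks of convolution, optional batch
#' normalization and ReLU, followed by global average pooling over time, a
#' dense penultimate layer of `feature_dim` units (the feature matrix `Z`
#' used by decorrelation training), and a single linear map to `n_classes`
#' logits with softmax output.
#'
#' @param n_channels Input channel count.
#' @param n_classes Number of classes `C`.
#' @param feature_dim Width `D` of the penultimate feature layer (default 64).
#' @param conv_widths Output channels per conv block.
#' @param kernel_sizes Kernel width per conv block.
#' @param strides Stride per conv block.
#' @param use_batch_norm Include a batch-norm layer after each convolution.
#'   Batch-norm layers are enumerable by name (see [model_layer_pool()]) so
#'   that DVERGE can sample post-batch-norm layers.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(n_channels, n_classes, feature_dim = 64L,
                            conv_widths = c(16L, 32L, 64L),
                            kernel_sizes = c(7L, 7L, 7L),
                            strides = c(4L, 4L, 2L),
                            use_batch_norm = TRUE, seed = 1L) {
  check_domain(is_count(n_channels), "`n_channels` must be a positive count")
  check_domain(is_count(n_classes) && n_classes >= 2,
               "`n_classes` must be >= 2")
  check_domain(is_count(feature_dim), "`feature_dim` must be a positive count")
  nb <- length(conv_widths)
  check_domain(nb >= 1 && length(kernel_sizes) == nb && length(strides) == nb,
               "`conv_widths`, `kernel_sizes`, `strides` must have equal length >= 1")
  structure(
    list(n_channels = as.integer(n_channels), n_classes = as.integer(n_classes),
         feature_dim = as.integer(feature_dim),
         conv_widths = as.integer(conv_widths),
         kernel_sizes = as.integer(kernel_sizes),
         strides = as.integer(strides),
         use_batch_norm = isTRUE(use_batch_norm), seed = as.integer(seed)),
    class = "classifier_spec")
}

#' Initialize a classifier from its specification
#'
#' Weights use He-style fan-in scaling; batch-norm running statistics start
#' at mean 0, variance 1. Initialization is a pure function of the spec
#' (including its seed).
#'
#' @param spec A [classifier_spec()].
#' @return An object of class `ecg_classifier`.
#' @export
init_classifier <- function(spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  nb <- length(spec$conv_widths)
  params <- list(conv = vector("list", nb), bn = vector("list", nb))
  state <- list(bn = vector("list", nb))
  cin <- spec$n_channels
  for (b in seq_len(nb)) {
    cout <- spec$conv_widths[b]; kw <- spec$kernel_sizes[b]
    fan_in <- cin * kw
    params$conv[[b]] <- list(
      W = matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout),
      b = numeric(cout))
    if (spec$use_batch_norm) {
      params$bn[[b]] <- list(gamma = rep(1, cout), beta = numeric(cout))
      state$bn[[b]] <- list(mean = numeric(cout), var = rep(1, cout))
    }
    cin <- cout
  }
  d <- spec$feature_dim
  params$fc_feat <- list(
    W = matrix(rnorm(cin * d, sd = sqrt(2 / cin)), cin, d),
    b = numeric(d))
  params$fc_out <- list(
    W = matrix(rnorm(d * spec$n_classes, sd = sqrt(2 / d)), d, spec$n_classes),
    b = numeric(spec$n_classes))
  structure(list(spec = spec, params = params, state = state),
            class = "ecg_classifier")
}

#' @export
print.ecg_classifier <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<ecg_classifier> %d conv block(s) %s, D=%d, C=%d%s\n",
              length(s$conv_widths),
              paste(s$conv_widths, collapse = "-"),
              s$feature_dim, s$n_classes,
              if (s$use_batch_norm) ", batch-norm" else ""))
  invisible(x)
}

#' Layer names available for DVERGE distillation
#'
#' Returns the post-batch-norm layer names (`"bn1"`, `"bn2"`, ...) when the
#' model uses batch normalization, otherwise the conv output names.
#'
#' @param model An `ecg_classifier`.
#' @return Character vector of layer names.
#' @export
model_layer_pool <- function(model) {
  nb <- length(model$spec$conv_widths)
  prefix <- if (model$spec$use_batch_norm) "bn" else "conv"
  paste0(prefix, seq_len(nb))
}

#' Class probabilities from a single classifier
#'
#' Runs the model in evaluation mode (batch norm uses running statistics),
#' so the output is deterministic for fixed weights and input.
#'
#' @param model An `ecg_classifier` (or `linear_softmax` test model).
#' @param batch A [signal_batch()] or bare `N x channels x T` array.
#' @return `N x C` matrix of class probabilities; each row sums to 1.
#' @export
predict_member <- function(model, batch) {
  UseMethod("predict_member")
}

#' @export
predict_member.ecg_classifier <- function(model, batch) {
  x <- batch_signals(batch)
  nn_forward(model, x, training = FALSE)$probs
}

batch_signals <- function(batch) {
  if (inherits(batch, "signal_batch")) batch$signals else batch
}

#' Extract penultimate-layer features
#'
#' Returns the `N x D` activation matrix of the dense feature layer that
#' feeds the final linear map, in evaluation mode. `activation = "post"`
#' (default) returns the post-ReLU values the final linear layer actually
#' consumes; `"pre"` returns the pre-activation values.
#'
#' @param model An `ecg_classifier`.
#' @param batch A [signal_batch()] or `N x channels x T` array.
#' @param activation `"post"` or `"pre"`.
#' @return `N x D` numeric matrix with `record_ids` attribute when the input
#'   is a `signal_batch`.
#' @export
extract_features <- function(model, batch, activation = c("post", "pre")) {
  activation <- match.arg(activation)
  x <- batch_signals(batch)
  fwd <- nn_forward(model, x, training = FALSE)
  z <- if (activation == "post") fwd$features else fwd$cache$h
  if (inherits(batch, "signal_batch")) attr(z, "record_ids") <- batch$record_ids
  z
}

# ---- Linear-softmax reference model ---------------------------------------

#' A bare linear-softmax model on flattened signals
#'
#' A minimal differentiable classifier (`logits = W' vec(x) + b`) used in
#' examples and as an analytically tractable attack target: the
#' cross-entropy input gradient has the closed form
#' `W (softmax(logits) - onehot(y))` reshaped to the signal grid.
#'
#' @param W `(channels * T) x C` weight matrix; rows ordered like
#'   `as.vector(x[n, , ])` (channel index varying fastest).
#' @param b Length-`C` bias.
#' @param n_channels,t_len Signal geometry.
#' @return An object of class `linear_softmax`.
#' @export
linear_softmax <- function(W, b, n_channels, t_len) {
  check_that(nrow(W) == n_channels * t_len, "W rows must equal channels * T")
  structure(list(W = W, b = b, n_channels = as.integer(n_channels),
                 t_len = as.integer(t_len), n_classes = ncol(W)),
            class = "linear_softmax")
}

flatten_signals <- function(x) {
  d <- dim(x)
  m <- matrix(0, d[1L], d[2L] * d[3L])
  for (i in seq_len(d[1L])) m[i, ] <- as.vector(x[i, , ])
  m
}

#' @export
predict_member.linear_softmax <- function(model, batch) {
  x <- batch_signals(batch)
  logits <- add_bias(flatten_signals(x) %*% model$W, model$b)
  row_softmax(logits)
}

# Cross-entropy input gradient for any supported target model (evaluation
# mode). Returns the per-sample gradient array in (N, C, T) layout along with
# the mean loss.
ce_input_gradient <- function(model, x, labels) {
  UseMethod("ce_input_gradient")
}

#' @export
ce_input_gradient.ecg_classifier <- function(model, x, labels) {
  fwd <- nn_forward(model, x, training = FALSE)
  cg <- ce_loss_grad(fwd$logits, fwd$probs, labels)
  bwd <- nn_backward(model, fwd$cache, dlogits = cg$dlogits,
                     need_input_grad = TRUE, need_param_grads = FALSE)
  list(loss = cg$loss, dx = bwd$dx)
}

#' @export
ce_input_gradient.linear_softmax <- function(model, x, labels) {
  d <- dim(x)
  flat <- flatten_signals(x)
  logits <- add_bias(flat %*% model$W, model$b)
  probs <- row_softmax(logits)
  cg <- ce_loss_grad(logits, probs, labels)
  dflat <- cg$dlogits %*% t(model$W)
  dx <- array(0, d)
  for (i in seq_len(d[1L])) dx[i, , ] <- matrix(dflat[i, ], d[2L], d[3L])
  list(loss = cg$loss, dx = dx)
}
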