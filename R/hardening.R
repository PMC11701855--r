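#' Hardening (adversarial / DVERGE training) configuration
#'
#' @param epsilon Inner-perturbation radius in signal-amplitude units
#'   (>= 0; zero disables the inner perturbation).
#' @param inner_steps Signed-gradient steps of the inner optimization
#'   (default 20, matching the attack convention; step size `epsilon / 10`).
#' @param budget_epochs Extra training epochs spent hardening each member
#'   (an epoch budget rather than a wall-clock one, for portability).
#' @param distill_layer_pool Layer names DVERGE samples from; default the
#'   post-batch-norm layers of the member being distilled.
#' @param domain_bounds Optional `c(lo, hi)` signal-domain bounds for the
#'   inner perturbations.
#' @param seed Integer seed for the hardening passes.
#' @return An object of class `hardening_config`.
#' @export
hardening_config <- function(epsilon, inner_steps = 20L, budget_epochs = 1L,
                             distill_layer_pool = NULL, domain_bounds = NULL,
                             seed = 1L) {
  check_domain(is_scalar_num(epsilon) && epsilon >= 0,
               "`epsilon` must be >= 0")
  check_domain(is_count(inner_steps, positive = FALSE) && inner_steps >= 0,
               "`inner_steps` must be >= 0")
  check_domain(is_count(budget_epochs), "`budget_epochs` must be >= 1")
  structure(list(epsilon = epsilon, inner_steps = as.integer(inner_steps),
                 budget_epochs = as.integer(budget_epochs),
                 distill_layer_pool = distill_layer_pool,
                 domain_bounds = domain_bounds, seed = as.integer(seed)),
            class = "hardening_config")
}

#' Adversarial training pass over one (pre-trained) member
#'
#' Identical to plain training except that every mini-batch is first
#' perturbed by PGD targeting the model being trained (single-model mode,
#' `epsilon`-ball, step size `epsilon / 10`), and the cross-entropy step is
#' taken on the perturbed batch. For partitioned members the perturbation
#' is crafted in raw input space through the member's filter.
#'
#' @param model A naturally trained `ecg_classifier`.
#' @param batch Labeled training [signal_batch()].
#' @param hconfig A [hardening_config()].
#' @param tconfig A [train_config()]; `epochs` is ignored in favor of
#'   `hconfig$budget_epochs`.
#' @param transform Optional `band_transform` (the member's partition
#'   filter).
#' @return List with the hardened `model` and a per-epoch loss `trace`.
#' @export
adversarial_training_pass <- function(model, batch, hconfig, tconfig,
                                      transform = NULL) {
  signals <- batch$signals
  labels <- batch$labels
  n <- length(labels)
  acfg <- attack_config(epsilon = hconfig$epsilon,
                        alpha = if (hconfig$epsilon > 0) hconfig$epsilon / 10 else 1,
                        n_steps = hconfig$inner_steps,
                        domain_bounds = hconfig$domain_bounds,
                        target_mode = "single_model", target_index = 0L)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(hconfig$seed, 311L))

  opt <- adam_init(model$params)
  trace <- vector("list", hconfig$budget_epochs)
  for (ep in seq_len(hconfig$budget_epochs)) {
    ord <- sample.int(n)
    ce_sum <- 0; nb <- 0L
    for (start in seq.int(1L, n, by = tconfig$batch_size)) {
      idx <- ord[start:min(start + tconfig$batch_size - 1L, n)]
      xb <- signals[idx, , , drop = FALSE]
      yb <- labels[idx]
      grad_fn <- function(x, k1) {
        xm <- apply_transform(transform, x)
        g <- ce_input_gradient(model, xm, yb)$dx
        if (!is.null(transform)) g <- apply_transform(transform, g)
        g
      }
      xb_adv <- pgd_core(grad_fn, xb, acfg, 1L)
      assert_ball(xb_adv - xb, hconfig$epsilon)
      step <- decorrelated_training_step(model, apply_transform(transform, xb_adv),
                                         yb, list(), decorr_config(), opt,
                                         tconfig$learning_rate)
      model <- step$model
      opt <- step$opt_state
      ce_sum <- ce_sum + step$ce
      nb <- nb + 1L
    }
    trace[[ep]] <- tibble::tibble(epoch = ep, ce = ce_sum / nb)
  }
  list(model = model, trace = dplyr::bind_rows(trace))
}

#' Harden every ensemble member by sequential adversarial training
#'
#' Members are hardened one after another, each against perturbations
#' targeting itself; the ensemble topology (member count, specs, input
#' transforms) is unchanged.
#'
#' @param ensemble A naturally trained `ecg_ensemble`.
#' @inheritParams adversarial_training_pass
#' @return The hardened `ecg_ensemble`.
#' @export
harden_ensemble_adversarial <- function(ensemble, batch, hconfig, tconfig) {
  for (k in seq_len(n_members(ensemble))) {
    hk <- hconfig
    hk$seed <- derive_seed(hconfig$seed, 1000L + k)
    res <- adversarial_training_pass(ensemble$members[[k]], batch, hk, tconfig,
                                     transform = ensemble$input_transforms[[k]])
    ensemble$members[[k]] <- res$model
  }
  ensemble
}

# ---- DVERGE ----------------------------------------------------------------

layer_block_index <- function(model, layer) {
  pool <- model_layer_pool(model)
  check_that(layer %in% pool,
             sprintf("layer '%s' not in the distillation pool (%s)",
                     layer, paste(pool, collapse = ", ")))
  as.integer(sub("^(bn|conv)", "", layer))
}

#' DVERGE feature distillation of one sample onto another
#'
#' Approximates `argmin_z || f_i^l(z) - f_i^l(x) ||^2` subject to
#' `||z - xs||_inf <= epsilon` by `inner_steps` signed-gradient descent
#' steps projected onto the ball around `xs`, starting from `z = xs`: the
#' result carries the non-robust layer-`l` features of `x` inside a small
#' neighborhood of `xs`.
#'
#' @param model The `ecg_classifier` whose features are distilled.
#' @param x `N x channels x T` array of feature-source samples.
#' @param xs Same-shape array of carrier samples (the perturbation base).
#' @param layer Layer name from [model_layer_pool()].
#' @param hconfig A [hardening_config()].
#' @param transform Optional `band_transform` applied inside the model's
#'   input graph.
#' @return The distilled array `z`, same shape as `xs`.
#' @export
dverge_distill_sample <- function(model, x, xs, layer, hconfig,
                                  transform = NULL) {
  check_that(identical(dim(x), dim(xs)), "`x` and `xs` must share shape")
  b <- layer_block_index(model, layer)
  target_act <- nn_forward(model, apply_transform(transform, x),
                           training = FALSE, upto = layer)$layer_out
  z <- xs
  eps <- hconfig$epsilon
  if (eps == 0 || hconfig$inner_steps == 0L) return(z)
  alpha <- eps / 10
  for (i in seq_len(hconfig$inner_steps)) {
    fw <- nn_forward(model, apply_transform(transform, z), training = FALSE,
                     upto = layer)
    diff <- fw$layer_out - target_act
    bw <- nn_backward(model, fw$cache,
                      inject = list(block = b, grad = 2 * diff),
                      need_input_grad = TRUE, need_param_grads = FALSE)
    g <- bw$dx
    if (!is.null(transform)) g <- apply_transform(transform, g)
    z <- clip_ball(z - alpha * sign(g), xs, eps)
    z <- clip_domain(z, hconfig$domain_bounds)
  }
  assert_ball(z - xs, eps)
  z
}

#' Draw, for each record, a partner record with a different label
#'
#' Partners are drawn uniformly from the full index set and resampled until
#' the label constraint `y != ys` holds; the resample count is reported.
#' Uses the current random stream.
#'
#' @param labels Integer label vector (the `ys` of the carrier records).
#' @param pool_labels Labels of the records partners are drawn from
#'   (default `labels`).
#' @return List with integer `partners` (indices into the pool) and
#'   `resamples` (number of redraws needed).
#' @export
draw_mismatched_pairs <- function(labels, pool_labels = labels) {
  check_that(length(unique(pool_labels)) >= 2,
             "cannot form label-mismatched pairs from a single-class pool")
  n <- length(labels)
  partners <- sample.int(length(pool_labels), n, replace = TRUE)
  resamples <- 0L
  repeat {
    bad <- which(pool_labels[partners] == labels)
    if (length(bad) == 0L) break
    partners[bad] <- sample.int(length(pool_labels), length(bad), replace = TRUE)
    resamples <- resamples + length(bad)
  }
  list(partners = partners, resamples = resamples)
}

#' Uniform draw from a distillation layer pool
#'
#' @param pool Character vector of layer names.
#' @return One layer name, drawn uniformly from the current random stream.
#' @export
sample_distill_layer <- function(pool) {
  check_that(length(pool) >= 1, "empty layer pool")
  pool[sample.int(length(pool), 1L)]
}

#' One DVERGE training round over an ensemble
#'
#' Per mini-batch: the distilling member `i` rotates round-robin; every
#' carrier record `xs` is paired with a feature-source record `x` whose
#' label differs (`y != ys`, resampled within the epoch if a draw
#' collides); a distillation layer is drawn uniformly from the
#' post-batch-norm pool; distilled inputs are built with member `i` and all
#' members `j != i` take one cross-entropy step on the distilled inputs
#' labeled `ys`. The ensemble topology is unchanged.
#'
#' @param ensemble A naturally trained `ecg_ensemble` with `K >= 2`.
#' @param batch Labeled training [signal_batch()].
#' @param hconfig A [hardening_config()].
#' @param tconfig A [train_config()].
#' @return List with the updated `ensemble` and a `stats` tibble (per-batch
#'   distiller index, layer, pair resample count).
#' @export
dverge_training_round <- function(ensemble, batch, hconfig, tconfig) {
  k_tot <- n_members(ensemble)
  check_that(k_tot >= 2, "DVERGE needs at least two members")
  signals <- batch$signals
  labels <- batch$labels
  n <- length(labels)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(hconfig$seed, 401L))

  opts <- lapply(ensemble$members, function(m) adam_init(m$params))
  stats <- list()
  ord <- sample.int(n)
  bi <- 0L
  for (start in seq.int(1L, n, by = tconfig$batch_size)) {
    idx <- ord[start:min(start + tconfig$batch_size - 1L, n)]
    bi <- bi + 1L
    i <- (bi - 1L) %% k_tot + 1L            # rotating distiller
    ys <- labels[idx]
    pair <- draw_mismatched_pairs(ys, pool_labels = labels)
    x_src <- signals[pair$partners, , , drop = FALSE]
    xs <- signals[idx, , , drop = FALSE]
    layer <- sample_distill_layer(hconfig$distill_layer_pool %||%
                                    model_layer_pool(ensemble$members[[i]]))
    z <- dverge_distill_sample(ensemble$members[[i]], x_src, xs, layer, hconfig,
                               transform = ensemble$input_transforms[[i]])
    for (j in seq_len(k_tot)) {
      if (j == i) next
      zj <- apply_transform(ensemble$input_transforms[[j]], z)
      step <- decorrelated_training_step(ensemble$members[[j]], zj, ys, list(),
                                         decorr_config(), opts[[j]],
                                         tconfig$learning_rate)
      ensemble$members[[j]] <- step$model
      opts[[j]] <- step$opt_state
    }
    stats[[bi]] <- tibble::tibble(batch = bi, distiller = i - 1L,
                                  layer = layer, resamples = pair$resamples)
  }
  list(ensemble = ensemble, stats = dplyr::bind_rows(stats))
}
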