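#' Adversarial attack configuration
#'
#' Parameters of the l-infinity attacks: the perturbation budget `epsilon`
#' (same units as the signal amplitude), the step size `alpha` (default
#' `epsilon / 10`), the iteration count (default 20), optional domain bounds
#' applied after the epsilon-ball projection at every step, and the target
#' mode: `"single_model"` attacks one designated member (default the first
#' model, the one trained first), `"ensemble_alternating"` rotates the
#' targeted member every iteration, optimizing the Jensen upper bound on the
#' ensemble cross-entropy.
#'
#' @param epsilon Perturbation radius (>= 0).
#' @param alpha Step size (> 0 when `epsilon > 0`).
#' @param n_steps Number of iterations (>= 0).
#' @param domain_bounds Optional `c(lo, hi)` clipping bounds for the signal
#'   domain (e.g. `c(-1, 1)`).
#' @param target_mode `"single_model"` or `"ensemble_alternating"`.
#' @param target_index Zero-based member index attacked in
#'   `"single_model"` mode (default 0, the first-trained model).
#' @param seed Optional integer seed recorded in provenance (the attacks
#'   themselves are deterministic).
#' @return An object of class `attack_config`.
#' @export
attack_config <- function(epsilon, alpha = epsilon / 10, n_steps = 20L,
                          domain_bounds = NULL,
                          target_mode = c("ensemble_alternating",
                                          "single_model"),
                          target_index = 0L, seed = NULL) {
  target_mode <- match.arg(target_mode)
  check_domain(is_scalar_num(epsilon) && epsilon >= 0, "`epsilon` must be >= 0")
  if (epsilon > 0) check_domain(is_scalar_num(alpha) && alpha > 0,
                                "`alpha` must be > 0 when `epsilon` > 0")
  check_domain(is_count(n_steps, positive = FALSE) && n_steps >= 0,
               "`n_steps` must be >= 0")
  if (!is.null(domain_bounds)) {
    check_domain(length(domain_bounds) == 2 && domain_bounds[1] < domain_bounds[2],
                 "`domain_bounds` must be c(lo, hi) with lo < hi")
  }
  structure(list(epsilon = epsilon, alpha = alpha, n_steps = as.integer(n_steps),
                 domain_bounds = domain_bounds, target_mode = target_mode,
                 target_index = as.integer(target_index), seed = seed),
            class = "attack_config")
}

#' Alternating-target schedule for ensemble attacks
#'
#' Member targeted at iteration `i` (zero-based): `i %% K`. With `K = 1`
#' this reduces to single-model attacking.
#'
#' @param i Zero-based iteration index (vectorized).
#' @param k Number of ensemble members (>= 1).
#' @return Zero-based member index (same length as `i`).
#' @export
alternating_target_schedule <- function(i, k) {
  check_that(is_count(k), "`k` must be >= 1")
  as.integer(i) %% as.integer(k)
}

# Coerce any supported attack target into an ensemble view.
as_target_ensemble <- function(target) {
  if (inherits(target, "ecg_ensemble")) target else new_ensemble(list(target))
}

# Cross-entropy input gradient through member k (1-based), including the
# member's input transform: the ring filters are zero-phase with real
# responses, hence self-adjoint, so the pullback is the same filter applied
# to the gradient.
member_ce_gradient <- function(ensemble, k, x, labels) {
  tr <- ensemble$input_transforms[[k]]
  g <- ce_input_gradient(ensemble$members[[k]], apply_transform(tr, x), labels)
  if (!is.null(tr)) g$dx <- apply_transform(tr, g$dx)
  g
}

clip_ball <- function(x, center, eps) pmin(pmax(x, center - eps), center + eps)

clip_domain <- function(x, bounds) {
  if (is.null(bounds)) x else pmin(pmax(x, bounds[1]), bounds[2])
}

# Shared PGD iteration core over an arbitrary per-step gradient function.
pgd_core <- function(grad_fn, x0, config, k_members) {
  xp <- x0
  if (config$epsilon == 0 || config$n_steps == 0L) return(xp)
  for (i in seq_len(config$n_steps) - 1L) {
    k <- if (config$target_mode == "ensemble_alternating") {
      alternating_target_schedule(i, k_members)
    } else {
      config$target_index
    }
    g <- grad_fn(xp, k + 1L)
    check_that(all(is.finite(g)), "non-finite attack gradient",
               class = "decorrens_numeric_error")
    xp <- xp + config$alpha * sign(g)
    xp <- clip_ball(xp, x0, config$epsilon)
    xp <- clip_domain(xp, config$domain_bounds)
  }
  xp
}

assert_ball <- function(delta, eps) {
  check_that(max(abs(delta)) <= eps + 1e-9,
             "internal error: perturbation escaped the epsilon ball")
}

#' Projected gradient descent attack
#'
#' Iterates `x' <- Clip_eps(x' + alpha * sign(grad_x CE))`, projecting after
#' every step first onto the l-infinity ball of radius `epsilon` around the
#' clean input and then onto the signal domain bounds, if set. The gradient
#' is taken through the targeted member (including its partition filter, for
#' partitioned ensembles); in `"ensemble_alternating"` mode the target
#' rotates every iteration. With `epsilon = 0` or `n_steps = 0` the input is
#' returned exactly.
#'
#' @param target An `ecg_ensemble`, `ecg_classifier`, or `linear_softmax`.
#' @param batch A labeled [signal_batch()].
#' @param config An [attack_config()].
#' @return A [signal_batch()] of perturbed signals (labels and ids
#'   unchanged) with a `provenance` attribute recording the attack
#'   parameters.
#' @export
pgd_attack <- function(target, batch, config) {
  ens <- as_target_ensemble(target)
  x0 <- batch$signals
  y <- batch$labels
  grad_fn <- function(x, k1) member_ce_gradient(ens, k1, x, y)$dx
  xp <- pgd_core(grad_fn, x0, config, n_members(ens))
  assert_ball(xp - x0, config$epsilon)
  out <- with_signals(batch, xp)
  attr(out, "provenance") <- list(method = "pgd", epsilon = config$epsilon,
                                  alpha = config$alpha, steps = config$n_steps,
                                  target_mode = config$target_mode,
                                  target_index = config$target_index,
                                  seed = config$seed)
  out
}

# ---- Smooth adversarial perturbations -------------------------------------

#' Build a bank of normalized Gaussian smoothing kernels
#'
#' Kernel `m` is a discretized Gaussian of odd width `widths[m]` and
#' standard deviation `sigmas[m]`, normalized to sum to 1 (hence symmetric
#' and constant-preserving). The published banks for the two ECG challenge
#' datasets are available via [physionet_kernel_bank()] and
#' [cpsc_kernel_bank()].
#'
#' @param widths Odd integer kernel widths.
#' @param sigmas Positive standard deviations, same length as `widths`.
#' @return An object of class `kernel_bank` with fields `widths`, `sigmas`,
#'   `kernels` (list of numeric vectors) and `m` (bank size).
#' @export
build_kernel_bank <- function(widths, sigmas) {
  check_domain(length(widths) == length(sigmas) && length(widths) >= 1,
               "`widths` and `sigmas` must have equal positive length")
  check_domain(all(widths %% 2 == 1), "kernel widths must be odd")
  check_domain(all(sigmas > 0), "kernel sigmas must be positive")
  kernels <- purrr::map2(as.integer(widths), sigmas, function(s, sigma) {
    half <- (s - 1L) / 2L
    k <- exp(-0.5 * ((-half):half / sigma)^2)
    k / sum(k)
  })
  structure(list(widths = as.integer(widths), sigmas = sigmas,
                 kernels = kernels, m = length(kernels)),
            class = "kernel_bank")
}

#' @rdname build_kernel_bank
#' @export
physionet_kernel_bank <- function() {
  build_kernel_bank(c(5L, 7L, 11L, 15L, 19L), c(1, 3, 5, 7, 10))
}

#' @rdname build_kernel_bank
#' @export
cpsc_kernel_bank <- function() {
  build_kernel_bank(c(9L, 11L, 15L, 19L, 21L), c(5, 7, 10, 13, 17))
}

# Reflected (mirror, no edge repeat) index for positions outside 1..t_len.
reflect_index <- function(idx, t_len) {
  if (t_len == 1L) return(rep(1L, length(idx)))
  period <- 2L * (t_len - 1L)
  m <- (idx - 1L) %% period
  m <- ifelse(m >= t_len, period - m, m)
  m + 1L
}

# Sparse T x T operator averaging the bank's reflect-padded convolutions.
# Built once per (bank, T); both the smoothing and its exact adjoint are a
# single sparse matrix product.
sap_smoother <- function(bank, t_len) {
  triplets_i <- integer(0); triplets_j <- integer(0); triplets_x <- numeric(0)
  for (m in seq_len(bank$m)) {
    k <- bank$kernels[[m]]
    half <- (bank$widths[m] - 1L) / 2L
    for (j in seq_along(k)) {
      off <- j - half - 1L
      cols <- reflect_index(seq_len(t_len) + off, t_len)
      triplets_i <- c(triplets_i, seq_len(t_len))
      triplets_j <- c(triplets_j, cols)
      triplets_x <- c(triplets_x, rep(k[j] / bank$m, t_len))
    }
  }
  Matrix::sparseMatrix(i = triplets_i, j = triplets_j, x = triplets_x,
                       dims = c(t_len, t_len))
}

# Apply a T x T operator along the time axis of an (N, C, T) array.
apply_time_operator <- function(x, op, transpose = FALSE) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1L] * d[2L], d[3L])
  y <- if (transpose) as.matrix(m %*% op) else as.matrix(Matrix::tcrossprod(m, op))
  dim(y) <- d
  y
}

#' Smooth adversarial perturbation (SAP) attack
#'
#' Optimizes a perturbation field `theta` with signed-gradient steps, but
#' the attacked input is `x + mean_m (theta convolved with Gaussian kernel
#' m)`: the kernel-bank smoothing is part of the differentiated graph, so
#' gradients are taken with respect to `theta` through the smoothing and the
#' optimized perturbation stays free of implausible high-frequency
#' artifacts. `theta` starts at zero and is clipped to the epsilon ball
#' after every step; since the kernels are nonnegative and sum-normalized,
#' the smoothed perturbation obeys the same bound. Target alternation
#' follows [alternating_target_schedule()]. The convolutions use
#' reflect padding, avoiding spike artifacts at the record edges.
#'
#' @inheritParams pgd_attack
#' @param bank A [build_kernel_bank()] kernel bank.
#' @return A perturbed [signal_batch()] with provenance, as [pgd_attack()].
#' @export
sap_attack <- function(target, batch, config, bank = physionet_kernel_bank()) {
  ens <- as_target_ensemble(target)
  x0 <- batch$signals
  y <- batch$labels
  d <- dim(x0)
  theta <- array(0, d)
  if (config$epsilon > 0 && config$n_steps > 0L) {
    smoother <- sap_smoother(bank, d[3L])
    for (i in seq_len(config$n_steps) - 1L) {
      k <- if (config$target_mode == "ensemble_alternating") {
        alternating_target_schedule(i, n_members(ens))
      } else {
        config$target_index
      }
      xs <- x0 + apply_time_operator(theta, smoother)
      g_x <- member_ce_gradient(ens, k + 1L, xs, y)$dx
      check_that(all(is.finite(g_x)), "non-finite attack gradient",
                 class = "decorrens_numeric_error")
      g_theta <- apply_time_operator(g_x, smoother, transpose = TRUE)
      theta <- clip_ball(theta + config$alpha * sign(g_theta), 0, config$epsilon)
    }
    xp <- x0 + apply_time_operator(theta, smoother)
  } else {
    xp <- x0
  }
  assert_ball(theta, config$epsilon)
  xp <- clip_domain(xp, config$domain_bounds)
  out <- with_signals(batch, xp)
  attr(out, "provenance") <- list(method = "sap", epsilon = config$epsilon,
                                  alpha = config$alpha, steps = config$n_steps,
                                  target_mode = config$target_mode,
                                  target_index = config$target_index,
                                  widths = bank$widths, sigmas = bank$sigmas,
                                  seed = config$seed)
  out
}

#' Craft an attacked copy of a batch by method name
#'
#' Convenience dispatcher used by the evaluation pipeline and command-line
#' interface.
#'
#' @param method `"pgd"` or `"sap"`.
#' @inheritParams pgd_attack
#' @param bank Kernel bank for SAP.
#' @return A perturbed [signal_batch()].
#' @export
craft_attack <- function(method, target, batch, config,
                         bank = physionet_kernel_bank()) {
  switch(method,
         pgd = pgd_attack(target, batch, config),
         sap = sap_attack(target, batch, config, bank),
         rlang::abort(sprintf("unknown attack method '%s'", method),
                      class = "decorrens_domain_error"))
}
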