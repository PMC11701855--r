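# Internal neural-network engine: a compact 1D CNN with hand-written
# forward/backward passes over base matrix ops. Activations are held in
# (N, T, C) layout internally; the public signal layout is (N, C, T).
#
# Architecture: [conv -> (batch norm) -> ReLU] x B -> global average pool
# -> dense feature layer (D units, ReLU) -> linear -> softmax.
# The post-activation output of the dense feature layer is the penultimate
# feature matrix Z used by decorrelation; batch-norm outputs are the layer
# pool sampled by DVERGE distillation.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

conv_out_len <- function(t_in, kw, stride) floor((t_in - kw) / stride) + 1L

# im2col: (N, T, C) -> matrix (N*To, C*kw); column block j holds the C
# channels at kernel offset j.
im2col <- function(a, kw, stride) {
  d <- dim(a)
  n <- d[1L]; t_in <- d[2L]; cin <- d[3L]
  to <- conv_out_len(t_in, kw, stride)
  check_that(to >= 1,
             sprintf("signal too short for the conv stack (length %d < kernel %d)",
                     t_in, kw))
  xcol <- array(numeric(n * to * cin * kw), c(n, to, cin * kw))
  for (j in seq_len(kw)) {
    idx <- seq.int(j, by = stride, length.out = to)
    xcol[, , (j - 1L) * cin + seq_len(cin)] <- a[, idx, , drop = FALSE]
  }
  dim(xcol) <- c(n * to, cin * kw)
  attr(xcol, "geom") <- c(n = n, t_in = t_in, cin = cin, to = to,
                          kw = kw, stride = stride)
  xcol
}

# Adjoint of im2col: scatter-add column gradients back onto the input grid.
col2im <- function(dxcol, geom) {
  n <- geom[["n"]]; t_in <- geom[["t_in"]]; cin <- geom[["cin"]]
  to <- geom[["to"]]; kw <- geom[["kw"]]; stride <- geom[["stride"]]
  dim(dxcol) <- c(n, to, cin * kw)
  da <- array(0, c(n, t_in, cin))
  for (j in seq_len(kw)) {
    idx <- seq.int(j, by = stride, length.out = to)
    da[, idx, ] <- da[, idx, ] + dxcol[, , (j - 1L) * cin + seq_len(cin)]
  }
  da
}

add_bias <- function(m, b) m + rep(b, each = nrow(m))

# Forward pass. `upto` may name a batch-norm ("bn2") or conv ("conv2") layer;
# the returned `layer_out` is that layer's output (pre-ReLU) and the cache is
# truncated there.
nn_forward <- function(model, x, training = FALSE, upto = NULL) {
  spec <- model$spec
  n <- dim(x)[1L]
  check_that(dim(x)[2L] == spec$n_channels,
             sprintf("batch has %d channel(s), model expects %d",
                     dim(x)[2L], spec$n_channels))
  a <- aperm(x, c(1L, 3L, 2L))              # (N, T, C)
  nb <- length(spec$conv_widths)
  blocks <- vector("list", nb)
  layer_out <- NULL
  for (b in seq_len(nb)) {
    kw <- spec$kernel_sizes[b]; s <- spec$strides[b]
    xcol <- im2col(a, kw, s)
    geom <- attr(xcol, "geom")
    cout <- spec$conv_widths[b]
    y <- xcol %*% model$params$conv[[b]]$W
    # conv bias is omitted under batch norm (the normalization absorbs it)
    if (!spec$use_batch_norm) y <- add_bias(y, model$params$conv[[b]]$b)
    blk <- list(xcol = xcol, geom = geom)
    if (spec$use_batch_norm) {
      st <- model$state$bn[[b]]
      gamma <- model$params$bn[[b]]$gamma; beta <- model$params$bn[[b]]$beta
      if (training) {
        mu <- colMeans(y)
        v <- colMeans(y * y) - mu^2
        std <- sqrt(v + BN_EPS)
        model$state$bn[[b]]$mean <- (1 - BN_MOMENTUM) * st$mean + BN_MOMENTUM * mu
        model$state$bn[[b]]$var <- (1 - BN_MOMENTUM) * st$var + BN_MOMENTUM * v
      } else {
        mu <- st$mean
        std <- sqrt(st$var + BN_EPS)
      }
      xhat <- (y - rep(mu, each = nrow(y))) / rep(std, each = nrow(y))
      y <- add_bias(xhat * rep(gamma, each = nrow(xhat)), beta)
      blk$bn <- list(xhat = xhat, std = std, training = training)
    }
    if (!is.null(upto) && upto %in% paste0(c("bn", "conv"), b)) {
      out <- y
      dim(out) <- c(geom[["n"]], geom[["to"]], cout)
      blocks[[b]] <- blk
      layer_out <- out
      return(list(layer_out = layer_out,
                  cache = list(blocks = blocks, upto = upto, upto_block = b,
                               n = n)))
    }
    a_out <- pmax(y, 0)
    dim(a_out) <- c(geom[["n"]], geom[["to"]], cout)
    blk$relu_mask <- y > 0
    blocks[[b]] <- blk
    a <- a_out
  }
  to <- dim(a)[2L]; clast <- dim(a)[3L]
  tmp <- aperm(a, c(2L, 1L, 3L))
  dim(tmp) <- c(to, n * clast)
  g <- matrix(colMeans(tmp), n, clast)      # global average pool
  h <- add_bias(g %*% model$params$fc_feat$W, model$params$fc_feat$b)
  feat <- pmax(h, 0)
  logits <- add_bias(feat %*% model$params$fc_out$W, model$params$fc_out$b)
  probs <- row_softmax(logits)
  list(probs = probs, logits = logits, features = feat,
       cache = list(blocks = blocks, g = g, h = h, feat = feat,
                    gap_t = to, n = n),
       model_state = model$state)
}

# Backward pass. Exactly one gradient source:
#  * `dlogits` (optionally plus `dfeat_extra` injected at the penultimate
#    feature layer), or
#  * `inject = list(block = k, grad = (N, To, C) array)` at block k's
#    batch-norm/conv output (pre-ReLU), as used by DVERGE distillation.
# Returns parameter gradients (same shape as params) and, when requested,
# the gradient with respect to the input in public (N, C, T) layout.
nn_backward <- function(model, cache, dlogits = NULL, dfeat_extra = NULL,
                        inject = NULL, need_input_grad = FALSE,
                        need_param_grads = TRUE) {
  spec <- model$spec
  nb <- length(spec$conv_widths)
  grads <- list(conv = vector("list", nb), bn = vector("list", nb))
  start_block <- nb
  da <- NULL

  if (is.null(inject)) {
    n <- cache$n
    dfeat <- tcrossprod(dlogits, model$params$fc_out$W)
    if (!is.null(dfeat_extra)) dfeat <- dfeat + dfeat_extra
    if (need_param_grads) {
      grads$fc_out <- list(W = crossprod(cache$feat, dlogits), b = colSums(dlogits))
    }
    dh <- dfeat * (cache$h > 0)
    if (need_param_grads) {
      grads$fc_feat <- list(W = crossprod(cache$g, dh), b = colSums(dh))
    }
    dg <- tcrossprod(dh, model$params$fc_feat$W)
    to <- cache$gap_t
    da <- aperm(array(dg / to, c(n, ncol(dg), to)), c(1L, 3L, 2L))
    relu_first <- TRUE
  } else {
    start_block <- inject$block
    da <- inject$grad
    relu_first <- FALSE                     # injected at pre-ReLU output
  }

  for (b in seq.int(start_block, 1L)) {
    blk <- cache$blocks[[b]]
    geom <- blk$geom
    cout <- spec$conv_widths[b]
    m <- geom[["n"]] * geom[["to"]]
    dy <- da
    dim(dy) <- c(m, cout)
    if (relu_first || b < start_block) dy <- dy * blk$relu_mask
    if (spec$use_batch_norm) {
      bn <- blk$bn
      gamma <- model$params$bn[[b]]$gamma
      if (need_param_grads) {
        grads$bn[[b]] <- list(gamma = colSums(dy * bn$xhat), beta = colSums(dy))
      }
      dxhat <- dy * rep(gamma, each = m)
      if (isTRUE(bn$training)) {
        mean_dxhat <- colMeans(dxhat)
        mean_dxhat_xhat <- colMeans(dxhat * bn$xhat)
        dy <- (dxhat - rep(mean_dxhat, each = m) -
                 bn$xhat * rep(mean_dxhat_xhat, each = m)) /
          rep(bn$std, each = m)
      } else {
        dy <- dxhat / rep(bn$std, each = m)
      }
    }
    if (need_param_grads) {
      grads$conv[[b]] <- list(W = crossprod(blk$xcol, dy),
                              b = if (spec$use_batch_norm) NULL else colSums(dy))
    }
    if (b > 1L || need_input_grad) {
      dxcol <- tcrossprod(dy, model$params$conv[[b]]$W)
      da <- col2im(dxcol, geom)
    }
  }
  dx <- if (need_input_grad) aperm(da, c(1L, 3L, 2L)) else NULL
  list(grads = grads, dx = dx)
}

# Cross-entropy from logits with zero-based integer labels. Returns the mean
# loss and its gradient w.r.t. the logits.
ce_loss_grad <- function(logits, probs, labels) {
  n <- nrow(logits)
  pick <- cbind(seq_len(n), labels + 1L)
  lse <- row_logsumexp(logits)
  loss <- mean(lse - logits[pick])
  dlogits <- probs
  dlogits[pick] <- dlogits[pick] - 1
  list(loss = loss, dlogits = dlogits / n)
}

# ---- Adam optimizer over nested parameter lists ----------------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
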