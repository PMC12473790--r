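# Elementary differentiable blocks shared by the pre-training and
# fine-tuning stages. Forward functions return caches; backward functions
# consume them. All follow the row-vector convention: activations are
# [B x d] matrices, weights [d_in x d_out].

# Exact (erf-form) GELU and its derivative.
gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

# Row-wise layer normalisation without learned affine terms; population
# variance with epsilon 1e-5. Returns y = (x - mean) / sqrt(var + eps)
# and the inverse-sd needed by the backward pass.
ln_forward <- function(x, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  list(y = xc * inv, inv = inv)
}

ln_backward <- function(dy, cache) {
  y <- cache$y
  cache$inv * (dy - rowMeans(dy) - y * rowMeans(dy * y))
}

# Row-wise softmax with max-shift for stability.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Multi-class cross-entropy
#'
#' Mean negative log-softmax probability of the true class, computed with
#' the log-sum-exp shift for numerical stability.
#'
#' @param logits numeric matrix `[B, K]`.
#' @param labels integer vector of length B with values in `0..K-1`.
#' @return scalar loss.
#' @export
#' @examples
#' cross_entropy(matrix(0, 2, 3), c(0L, 2L))   # log(3)
cross_entropy <- function(logits, labels) {
  labels <- as.integer(labels)
  k <- ncol(logits)
  if (any(labels < 0L) || any(labels >= k)) {
    stop("labels must lie in 0..K-1", call. = FALSE)
  }
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  true_logit <- logits[cbind(seq_len(nrow(logits)), labels + 1L)]
  mean(lse - true_logit)
}

# Gradient of mean cross-entropy w.r.t. logits: (softmax - onehot) / B.
cross_entropy_grad <- function(logits, labels) {
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(nrow(logits)), as.integer(labels) + 1L)
  p[idx] <- p[idx] - 1
  p / nrow(logits)
}

# ---- gradient clipping ----------------------------------------------------

# Euclidean norm over a whole named list of gradient arrays.
global_grad_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
}

#' Clip gradients by global norm
#'
#' Scales every gradient array by `min(1, max_norm / ||g||_2)` where the
#' norm runs over the concatenation of all arrays, so the post-clip global
#' norm never exceeds `max_norm`. A zero gradient is returned unchanged
#' (no 0/0).
#'
#' @param grads named list of numeric arrays (or a single array).
#' @param max_norm clipping threshold (default 1.0).
#' @return list with `grads` (same structure, scaled) and `norm` (the
#'   pre-clip global norm).
#' @export
clip_gradients <- function(grads, max_norm = 1.0) {
  single <- !is.list(grads)
  gl <- if (single) list(g = grads) else grads
  nrm <- global_grad_norm(gl)
  if (nrm > max_norm && nrm > 0) {
    gl <- lapply(gl, function(g) g * (max_norm / nrm))
  }
  list(grads = if (single) gl$g else gl, norm = nrm)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- reduce-on-plateau scheduler ------------------------------------------

#' Reduce-on-plateau learning-rate scheduler
#'
#' State machine that multiplies the learning rate by `factor` once the
#' monitored loss has gone `patience` consecutive epochs without strict
#' improvement over the best value seen. After a reduction the bad-epoch
#' counter resets. Create with `plateau_scheduler()`, advance once per
#' epoch with `scheduler_step()`.
#'
#' @param lr initial learning rate.
#' @param factor multiplicative reduction (default 0.5).
#' @param patience epochs without improvement before reducing (default 5).
#' @param min_lr floor on the learning rate.
#' @return scheduler state list; `scheduler_step` returns the updated
#'   state with elements `lr`, `best`, `bad_epochs`, `n_reductions`.
#' @export
#' @examples
#' s <- plateau_scheduler(0.1, patience = 5)
#' for (e in 1:7) s <- scheduler_step(s, 1.0)  # flat loss
#' s$lr            # halved exactly once (after epoch 6)
plateau_scheduler <- function(lr, factor = 0.5, patience = 5L,
                              min_lr = 0) {
  stopifnot(lr > 0, factor > 0, factor < 1, patience >= 1)
  list(lr = lr, factor = factor, patience = as.integer(patience),
       min_lr = min_lr, best = Inf, bad_epochs = 0L, n_reductions = 0L)
}

#' @param state scheduler state.
#' @param loss monitored loss for the epoch that just finished.
#' @rdname plateau_scheduler
#' @export
scheduler_step <- function(state, loss) {
  if (loss < state$best) {
    state$best <- loss
    state$bad_epochs <- 0L
  } else {
    state$bad_epochs <- state$bad_epochs + 1L
    if (state$bad_epochs >= state$patience) {
      state$lr <- max(state$min_lr, state$lr * state$factor)
      state$n_reductions <- state$n_reductions + 1L
      state$bad_epochs <- 0L
    }
  }
  state
}
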