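#' Fine-tuning configuration
#'
#' Supervised stage-2 hyper-parameters. Published schedule: 20 epochs at
#' batch size 128 with global-norm gradient clipping at 1.0 and a
#' reduce-on-plateau learning-rate schedule (factor 0.5, patience 5)
#' monitoring the epoch-mean training loss.
#'
#' @param epochs training epochs (default 20).
#' @param batch_size samples per step (default 128).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param clip_norm global gradient-norm ceiling (default 1.0).
#' @param scheduler_factor,scheduler_patience plateau-scheduler settings
#'   (defaults 0.5 and 5).
#' @param seed RNG seed for batching and dropout.
#' @param amp accepted for interface compatibility; mixed-precision
#'   arithmetic is not performed (all computation is double precision)
#'   and the flag has no effect on results.
#' @return list of class `finetune_config`.
#' @export
finetune_config <- function(epochs = 20L, batch_size = 128L,
                            learning_rate = 1e-4, clip_norm = 1.0,
                            scheduler_factor = 0.5,
                            scheduler_patience = 5L, seed = 1L,
                            amp = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, clip_norm > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, clip_norm = clip_norm,
                 scheduler_factor = scheduler_factor,
                 scheduler_patience = as.integer(scheduler_patience),
                 seed = as.integer(seed), amp = isTRUE(amp)),
            class = "finetune_config")
}

#' Supervised fine-tuning of the dual-encoder model
#'
#' Minimises the cross-entropy of the classifier head on labelled target
#' fine-tune data with Adam; every step clips the global gradient norm to
#' `clip_norm`, and the plateau scheduler halves the learning rate after
#' `scheduler_patience` epochs without improvement of the epoch-mean
#' loss. Deterministic given `cfg$seed`.
#'
#' @param model a [dual_encoder_init()] model.
#' @param x numeric matrix `[N, d_input]` of normalised flat features.
#' @param y integer labels in `0..K-1`, length N.
#' @param cfg a [finetune_config()].
#' @return list of class `cate_finetune` with `model` (trained),
#'   `history` (tibble: epoch, loss, accuracy, lr, max_grad_norm — the
#'   largest post-clip global norm seen in the epoch) and `cfg`.
#' @export
run_finetuning <- function(model, x, y, cfg = finetune_config()) {
  y <- as.integer(y)
  k <- model$meta$n_classes
  if (any(y < 0L) || any(y >= k)) {
    stop("labels exceed the model's ", k, "-class head", call. = FALSE)
  }
  if (ncol(x) != model$meta$d_input) {
    stop("input width ", ncol(x), " does not match model d_input ",
         model$meta$d_input, call. = FALSE)
  }
  n <- nrow(x)
  set.seed(cfg$seed)
  opt <- adam_init(model$params)
  sched <- plateau_scheduler(cfg$learning_rate,
                             factor = cfg$scheduler_factor,
                             patience = cfg$scheduler_patience)
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    ep_loss <- 0; max_nrm <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1, n)]
      fw <- model_forward(model, x[idx, , drop = FALSE], training = TRUE)
      loss <- cross_entropy(fw$logits, y[idx])
      dlog <- cross_entropy_grad(fw$logits, y[idx])
      grads <- model_backward(model, fw$cache, dlog)
      cl <- clip_gradients(grads, cfg$clip_norm)
      max_nrm <- max(max_nrm, min(cl$norm, cfg$clip_norm))
      st <- adam_step(model$params, cl$grads, opt, lr = sched$lr)
      model$params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + loss * length(idx) / n
    }
    acc <- accuracy(predict(model, x), y)
    sched <- scheduler_step(sched, ep_loss)
    hist[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss,
                                 accuracy = acc, lr = sched$lr,
                                 max_grad_norm = max_nrm)
  }
  structure(list(model = model, history = dplyr::bind_rows(hist),
                 cfg = cfg),
            class = "cate_finetune")
}

#' @export
print.cate_finetune <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<cate_finetune> %d epochs | final train loss %.4f | train accuracy %.3f\n",
    x$cfg$epochs, last$loss, last$accuracy))
  invisible(x)
}
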