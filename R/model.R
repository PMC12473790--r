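# Stage-2 model: two parallel attention encoders (initialised from the
# pre-trained backbone) + averaging fusion + MLP classifier. DE vectors
# are sequences of length one, so the attention block reduces to the
# affine map H %*% W_V %*% W_O and pooling layers are identity maps; both
# are kept explicit for structural fidelity to the sequence formulation.

#' Initialise the dual-encoder fine-tuning model
#'
#' Builds the full stage-2 model. Both encoders' backbones are copies of
#' the *same* pre-trained extractor (or fresh random extractors when
#' `pretrained = NULL`, the "from scratch" ablation); the attention,
#' feed-forward and classifier weights are always freshly initialised.
#' Uses the global RNG.
#'
#' @param n_classes number of emotion classes K.
#' @param pretrained an [extractor_init()] parameter set (typically
#'   `run_pretraining(...)$params`), or `NULL` for random initialisation.
#' @param d_input flat input width (needed when `pretrained = NULL`).
#' @param d_model latent width (must match `pretrained` if given).
#' @param h attention heads (default 4; must divide `d_model`).
#' @param d_hidden classifier hidden width (default 128).
#' @param alpha residual scaling factor (default 0.1).
#' @param dropout dropout rate in the feed-forward block and classifier
#'   head (default 0.1; active only during training).
#' @return list of class `dual_encoder_model` with `params` (flat named
#'   list of arrays) and `meta`.
#' @export
dual_encoder_init <- function(n_classes, pretrained = NULL,
                              d_input = 310L, d_model = 256L, h = 4L,
                              d_hidden = 128L, alpha = 0.1,
                              dropout = 0.1) {
  if (!is.null(pretrained)) {
    d_input <- nrow(pretrained$W1)
    d_model <- length(pretrained$b1)
  }
  if (d_model %% h != 0) stop("d_model must be divisible by h", call. = FALSE)
  stopifnot(dropout >= 0, dropout < 1)
  bb <- function() {
    p <- if (is.null(pretrained)) extractor_init(d_input, d_model)
         else pretrained
    unclass(p)
  }
  att <- function() {
    a <- attention_params(d_model, h)
    list(W_Q = a$W_Q, W_K = a$W_K, W_V = a$W_V, W_O = a$W_O)
  }
  ffn <- function() list(
    Wf1 = matrix(rnorm(d_model * 4 * d_model, sd = 1 / sqrt(d_model)),
                 d_model, 4 * d_model),
    Wf2 = matrix(rnorm(4 * d_model * d_model, sd = 1 / sqrt(4 * d_model)),
                 4 * d_model, d_model))
  pfx <- function(lst, p) setNames(lst, paste0(p, names(lst)))
  params <- c(
    pfx(bb(), "nerm_bb_"), pfx(att(), "nerm_"),
    pfx(bb(), "wtrm_bb_"), pfx(att(), "wtrm_"), pfx(ffn(), "wtrm_"),
    list(cls_W1 = matrix(rnorm(d_model * d_hidden, sd = 1 / sqrt(d_model)),
                         d_model, d_hidden),
         cls_b1 = numeric(d_hidden),
         cls_W2 = matrix(rnorm(d_hidden * n_classes,
                               sd = 1 / sqrt(d_hidden)),
                         d_hidden, n_classes),
         cls_b2 = numeric(n_classes)))
  structure(
    list(params = params,
         meta = list(d_input = as.integer(d_input),
                     d_model = as.integer(d_model), h = as.integer(h),
                     d_hidden = as.integer(d_hidden),
                     n_classes = as.integer(n_classes),
                     alpha = alpha, dropout = dropout,
                     pretrained = !is.null(pretrained))),
    class = "dual_encoder_model")
}

#' @export
print.dual_encoder_model <- function(x, ...) {
  m <- x$meta
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<dual_encoder_model> d_input %d -> d_model %d (h=%d) -> %d classes | %s init | %d parameters\n",
    m$d_input, m$d_model, m$h, m$n_classes,
    if (m$pretrained) "pretrained" else "random", np))
  invisible(x)
}

# inverted-dropout mask (already scaled); identity when rate 0 or eval.
drop_mask <- function(dims, rate, training) {
  if (!training || rate <= 0) return(1)
  array((runif(prod(dims)) >= rate) / (1 - rate), dim = dims)
}

# ---- encoder forward/backward (L = 1 fast path) ---------------------------

encoder_forward <- function(x, params, meta, kind, training = FALSE) {
  p <- function(nm) params[[paste0(kind, "_", nm)]]
  bb <- list(W1 = p("bb_W1"), b1 = p("bb_b1"),
             W2 = p("bb_W2"), b2 = p("bb_b2"))
  fb <- extractor_forward(x, bb)
  h0 <- fb$z
  a <- (h0 %*% p("W_V")) %*% p("W_O")
  s <- h0 + meta$alpha * a
  ln1 <- ln_forward(s)
  cache <- list(bb = fb$cache, bbp = bb, h0 = h0, ln1 = ln1)
  if (kind == "nerm") {
    ln2 <- ln_forward(ln1$y)
    cache$ln2 <- ln2
    z <- ln2$y
  } else {
    t1 <- ln1$y %*% p("Wf1")
    d1 <- drop_mask(dim(t1), meta$dropout, training)
    t1d <- t1 * d1
    g <- gelu(t1d)
    t2 <- g %*% p("Wf2")
    d2 <- drop_mask(dim(t2), meta$dropout, training)
    hff <- ln1$y + meta$alpha * (t2 * d2)
    lnf <- ln_forward(hff)
    lnp <- ln_forward(lnf$y)
    cache <- c(cache, list(t1 = t1, d1 = d1, t1d = t1d, g = g, d2 = d2,
                           lnf = lnf, lnp = lnp))
    z <- lnp$y
  }
  list(z = z, cache = cache)
}

encoder_backward <- function(dz, cache, params, meta, kind) {
  p <- function(nm) params[[paste0(kind, "_", nm)]]
  grads <- list()
  if (kind == "nerm") {
    dln1 <- ln_backward(dz, cache$ln2)
  } else {
    dlnf <- ln_backward(dz, cache$lnp)
    dhff <- ln_backward(dlnf, cache$lnf)
    dt2d <- meta$alpha * dhff
    dt2 <- dt2d * cache$d2
    grads[[paste0(kind, "_Wf2")]] <- crossprod(cache$g, dt2)
    dg <- dt2 %*% t(p("Wf2"))
    dt1d <- dg * gelu_grad(cache$t1d)
    dt1 <- dt1d * cache$d1
    grads[[paste0(kind, "_Wf1")]] <- crossprod(cache$ln1$y, dt1)
    dln1 <- dhff + dt1 %*% t(p("Wf1"))
  }
  ds <- ln_backward(dln1, cache$ln1)
  # s = h0 + alpha * h0 W_V W_O ; softmax over one key contributes no
  # gradient to W_Q / W_K.
  da <- meta$alpha * ds
  hv <- cache$h0 %*% p("W_V")
  grads[[paste0(kind, "_W_O")]] <- crossprod(hv, da)
  dhv <- da %*% t(p("W_O"))
  grads[[paste0(kind, "_W_V")]] <- crossprod(cache$h0, dhv)
  grads[[paste0(kind, "_W_Q")]] <- p("W_Q") * 0
  grads[[paste0(kind, "_W_K")]] <- p("W_K") * 0
  dh0 <- ds + dhv %*% t(p("W_V"))
  gb <- extractor_backward(dh0, cache$bb, cache$bbp)
  grads[[paste0(kind, "_bb_W1")]] <- gb$W1
  grads[[paste0(kind, "_bb_b1")]] <- gb$b1
  grads[[paste0(kind, "_bb_W2")]] <- gb$W2
  grads[[paste0(kind, "_bb_b2")]] <- gb$b2
  grads
}

#' Encode with one view encoder
#'
#' Runs the named encoder branch of a fitted (or freshly initialised)
#' model on flat normalised features, in evaluation mode. `nerm_encode`
#' is the attention-only branch, `wtrm_encode` adds the feed-forward
#' refinement stage.
#'
#' @param x numeric matrix `[B, d_input]`.
#' @param model a [dual_encoder_init()] model.
#' @return embedding matrix `[B, d_model]`.
#' @export
nerm_encode <- function(x, model) {
  encoder_forward(x, model$params, model$meta, "nerm")$z
}

#' @rdname nerm_encode
#' @export
wtrm_encode <- function(x, model) {
  encoder_forward(x, model$params, model$meta, "wtrm")$z
}

#' Fuse the two view embeddings
#'
#' Element-wise average of the encoder outputs.
#'
#' @param z_nerm,z_wtrm matrices of identical shape.
#' @return their mean.
#' @export
fuse_views <- function(z_nerm, z_wtrm) {
  stopifnot(all(dim(z_nerm) == dim(z_wtrm)))
  (z_nerm + z_wtrm) / 2
}

# classifier head forward/backward
classifier_forward <- function(zf, params, meta, training = FALSE) {
  c1 <- sweep(zf %*% params$cls_W1, 2, params$cls_b1, "+")
  lnc <- ln_forward(c1)
  g <- gelu(lnc$y)
  dm <- drop_mask(dim(g), meta$dropout, training)
  hd <- g * dm
  logits <- sweep(hd %*% params$cls_W2, 2, params$cls_b2, "+")
  list(logits = logits,
       cache = list(zf = zf, c1 = c1, lnc = lnc, dm = dm, hd = hd))
}

classifier_backward <- function(dlogits, cache, params) {
  grads <- list(cls_b2 = colSums(dlogits),
                cls_W2 = crossprod(cache$hd, dlogits))
  dhd <- dlogits %*% t(params$cls_W2)
  dg <- dhd * cache$dm
  dlnc <- dg * gelu_grad(cache$lnc$y)
  dc1 <- ln_backward(dlnc, cache$lnc)
  grads$cls_b1 <- colSums(dc1)
  grads$cls_W1 <- crossprod(cache$zf, dc1)
  grads$dzf <- dc1 %*% t(params$cls_W1)
  grads
}

#' Classify fused embeddings
#'
#' MLP head: `W2 . Dropout(GELU(LayerNorm(W1 z + b1))) + b2` (dropout only
#' in training mode).
#'
#' @param z_fused matrix `[B, d_model]`.
#' @param model a [dual_encoder_init()] model.
#' @return logits matrix `[B, K]`.
#' @export
classify <- function(z_fused, model) {
  classifier_forward(z_fused, model$params, model$meta)$logits
}

# full model forward: x -> logits (+ caches for training)
model_forward <- function(model, x, training = FALSE) {
  fn <- encoder_forward(x, model$params, model$meta, "nerm", training)
  fw <- encoder_forward(x, model$params, model$meta, "wtrm", training)
  zf <- fuse_views(fn$z, fw$z)
  cl <- classifier_forward(zf, model$params, model$meta, training)
  list(logits = cl$logits,
       cache = list(nerm = fn$cache, wtrm = fw$cache, cls = cl$cache))
}

model_backward <- function(model, cache, dlogits) {
  gc <- classifier_backward(dlogits, cache$cls, model$params)
  dz <- gc$dzf / 2           # fusion is the mean of the two branches
  gc$dzf <- NULL
  gn <- encoder_backward(dz, cache$nerm, model$params, model$meta, "nerm")
  gw <- encoder_backward(dz, cache$wtrm, model$params, model$meta, "wtrm")
  grads <- c(gn, gw, gc)
  grads[names(model$params)]
}

#' Predict emotion labels
#'
#' Evaluation-mode forward pass followed by an argmax over logits.
#'
#' @param object a [dual_encoder_init()] model (typically after
#'   [run_finetuning()]).
#' @param x numeric matrix `[B, d_input]` of normalised flat features.
#' @param type `"class"` for 0-based labels, `"logits"` for the raw
#'   matrix, `"prob"` for softmax probabilities.
#' @param ... unused.
#' @return integer vector, or a matrix for `"logits"`/`"prob"`.
#' @export
predict.dual_encoder_model <- function(object, x, type = c("class",
                                       "logits", "prob"), ...) {
  type <- match.arg(type)
  logits <- model_forward(object, x)$logits
  switch(type,
         class = max.col(logits, ties.method = "first") - 1L,
         logits = logits,
         prob = softmax_rows(logits))
}
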