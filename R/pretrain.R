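#' Pre-training configuration
#'
#' Hyper-parameters of the dual-view self-supervised stage. Published
#' schedule: 200 epochs at batch size 256. The loss weights, width and
#' optimiser settings are the package defaults (the training recipe does
#' not pin them) and are all exposed here.
#'
#' @param lambda_align weight of the alignment loss (default 1).
#' @param lambda_style weight of the style-diversity loss (default 0.01).
#' @param epochs training epochs (default 200).
#' @param batch_size samples per step (default 256).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param d_model latent width of the shared extractor (default 256).
#' @param normalize_gram row-normalise embeddings in the Gram loss and
#'   scale it by `1/B^2` (default `TRUE`); `FALSE` selects the literal
#'   unnormalised Gram penalty.
#' @param seed RNG seed for initialisation, batching and the views.
#' @return list of class `pretrain_config`.
#' @export
pretrain_config <- function(lambda_align = 1.0, lambda_style = 0.01,
                            epochs = 200L, batch_size = 256L,
                            learning_rate = 1e-3, d_model = 256L,
                            normalize_gram = TRUE, seed = 1L) {
  stopifnot(lambda_align >= 0, lambda_style >= 0, epochs >= 1,
            batch_size >= 1, learning_rate > 0, d_model > 0)
  structure(list(lambda_align = lambda_align, lambda_style = lambda_style,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, d_model = as.integer(d_model),
                 normalize_gram = isTRUE(normalize_gram),
                 seed = as.integer(seed)),
            class = "pretrain_config")
}

#' Run dual-view self-supervised pre-training
#'
#' Trains the shared two-layer extractor. Every step draws fresh
#' augmented copies of the batch — by default a noise-enhanced (NERM) view
#' and a wavelet-perturbation (WTRM) view — pushes both through the *same*
#' parameters, and takes an Adam step on
#' `lambda_align * L_align + lambda_style * L_style`. Labels are never
#' used. Fully deterministic given `cfg$seed` (single-threaded BLAS).
#'
#' @param x input features: a [de_feature_set], an `[N, C, F]` array, or a
#'   flat `[N, C*F]` matrix (already normalised; the wavelet view operates
#'   on the `[N, C, F]` shape). Matrices are unflattened with
#'   `n_channels` inferred as `ncol/5`.
#' @param cfg a [pretrain_config()].
#' @param noise_cfg,wavelet_cfg,mask_cfg view configurations.
#' @param views length-2 character vector selecting the two views from
#'   `"nerm"`, `"wtrm"`, `"identity"`. Ablations replace the removed view
#'   with `"identity"` (the clean input).
#' @param params optional warm-start [extractor_init()] parameters.
#' @return list of class `cate_pretrain` with `params`
#'   (`extractor_params`), `history` (tibble: epoch, total, align, style),
#'   `cfg` and `views`.
#' @export
run_pretraining <- function(x, cfg = pretrain_config(),
                            noise_cfg = noise_config(),
                            wavelet_cfg = wavelet_config(),
                            mask_cfg = mask_config(),
                            views = c("nerm", "wtrm"),
                            params = NULL) {
  views <- match.arg(views, c("nerm", "wtrm", "identity"),
                     several.ok = TRUE)
  if (length(views) != 2L) stop("exactly two views are required",
                                call. = FALSE)
  xt <- as_feature_array(x)
  n <- dim(xt)[1]
  if (n < 1L) stop("empty dataset", call. = FALSE)
  set.seed(cfg$seed)
  if (is.null(params)) {
    params <- extractor_init(d_input = prod(dim(xt)[2:3]),
                             d_model = cfg$d_model)
  }
  opt <- adam_init(params)
  make_view <- function(kind, xb) {
    switch(kind,
           nerm = nerm_view(xb, noise_cfg),
           wtrm = wtrm_view(xb, wavelet_cfg, mask_cfg),
           identity = xb)
  }
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    ep_tot <- ep_al <- ep_st <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1, n)]
      xb <- xt[idx, , , drop = FALSE]
      v1 <- de_flatten(make_view(views[1], xb))
      v2 <- de_flatten(make_view(views[2], xb))
      f1 <- extractor_forward(v1, params)
      f2 <- extractor_forward(v2, params)
      loss <- pretrain_total_loss(f1$z, f2$z, cfg)
      ga <- alignment_loss_grad(f1$z, f2$z)
      gs <- style_diversity_grad(f1$z, f2$z,
                                 normalize_rows = cfg$normalize_gram,
                                 scale_by_batch = cfg$normalize_gram)
      dz1 <- cfg$lambda_align * ga$dz1 + cfg$lambda_style * gs$dz1
      dz2 <- cfg$lambda_align * ga$dz2 + cfg$lambda_style * gs$dz2
      g1 <- extractor_backward(dz1, f1$cache, params)
      g2 <- extractor_backward(dz2, f2$cache, params)
      grads <- Map(`+`, g1, g2)
      st <- adam_step(params, grads, opt, lr = cfg$learning_rate)
      params <- st$params
      opt <- st$state
      w <- length(idx) / n
      ep_tot <- ep_tot + w * loss$total
      ep_al <- ep_al + w * loss$align
      ep_st <- ep_st + w * loss$style
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, total = ep_tot,
                                 align = ep_al, style = ep_st)
  }
  structure(list(params = params,
                 history = dplyr::bind_rows(hist),
                 cfg = cfg, views = views),
            class = "cate_pretrain")
}

#' @export
print.cate_pretrain <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<cate_pretrain> views %s+%s | d_model %d | %d epochs | final loss %.4f\n",
    x$views[1], x$views[2], x$cfg$d_model, x$cfg$epochs, last$total))
  invisible(x)
}

# Accept feature sets, tensors or flat matrices uniformly.
as_feature_array <- function(x) {
  if (inherits(x, "de_feature_set")) return(x$values)
  if (is.matrix(x)) {
    if (ncol(x) %% 5L != 0)
      stop("flat width must be a multiple of 5 bands", call. = FALSE)
    return(de_unflatten(x, n_channels = ncol(x) %/% 5L, n_bands = 5L))
  }
  stopifnot(is.array(x), length(dim(x)) == 3L)
  x
}
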