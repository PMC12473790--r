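#' Initialise the shared feature extractor
#'
#' The backbone shared by both self-supervised views is a two-layer map
#' `Z = LayerNorm(GELU(X W1 + b1)) W2 + b2` applied row-wise to flat
#' feature vectors. Weights are drawn from scaled Gaussians
#' (`sd = 1/sqrt(fan_in)`), biases start at zero. Uses the global RNG.
#'
#' @param d_input flat input width (default 310 = 62 channels x 5 bands).
#' @param d_model latent width (default 256).
#' @return named list of class `extractor_params` with `W1 [d_input x
#'   d_model]`, `b1`, `W2 [d_model x d_model]`, `b2`.
#' @export
extractor_init <- function(d_input = 310L, d_model = 256L) {
  stopifnot(d_input > 0, d_model > 0)
  structure(
    list(W1 = matrix(rnorm(d_input * d_model, sd = 1 / sqrt(d_input)),
                     d_input, d_model),
         b1 = numeric(d_model),
         W2 = matrix(rnorm(d_model * d_model, sd = 1 / sqrt(d_model)),
                     d_model, d_model),
         b2 = numeric(d_model)),
    class = "extractor_params")
}

# Forward pass with cache for backprop.
extractor_forward <- function(x, params) {
  a1 <- sweep(x %*% params$W1, 2, params$b1, "+")
  g <- gelu(a1)
  ln <- ln_forward(g)
  z <- sweep(ln$y %*% params$W2, 2, params$b2, "+")
  list(z = z, cache = list(x = x, a1 = a1, ln = ln))
}

#' Extract latent features with the shared backbone
#'
#' Deterministic row-wise application of the two-layer extractor.
#'
#' @param x numeric matrix `[B, d_input]` of (normalised) flat features.
#' @param params an [extractor_init()] parameter set.
#' @return numeric matrix `[B, d_model]`.
#' @export
extract_features <- function(x, params) {
  if (ncol(x) != nrow(params$W1)) {
    stop("input width ", ncol(x), " does not match extractor d_input ",
         nrow(params$W1), call. = FALSE)
  }
  extractor_forward(x, params)$z
}

# Backward pass: gradient of a scalar loss w.r.t. params (and input).
extractor_backward <- function(dz, cache, params, want_dx = FALSE) {
  db2 <- colSums(dz)
  dW2 <- crossprod(cache$ln$y, dz)
  dy <- dz %*% t(params$W2)
  dg <- ln_backward(dy, cache$ln)
  da1 <- dg * gelu_grad(cache$a1)
  grads <- list(W1 = crossprod(cache$x, da1), b1 = colSums(da1),
                W2 = dW2, b2 = db2)
  if (want_dx) grads$x <- da1 %*% t(params$W1)
  grads
}
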