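#' Adaptive-noise view configuration
#'
#' Parameters of the noise-enhanced representation modelling (NERM) view.
#' The injected Gaussian noise has standard deviation
#' `min(cap, slope * mean(|X|) + eps)`, one scalar per batch, so the
#' perturbation tracks the magnitude of the features but is capped to
#' avoid corrupting the band-power structure.
#'
#' @param cap upper bound on the noise scale (default 0.05).
#' @param slope multiplier on the batch mean absolute value (default 0.1).
#' @param eps numerical-stability constant (default 1e-8); also the floor
#'   of the scale for an all-zero batch.
#' @return list of class `noise_config`.
#' @export
noise_config <- function(cap = 0.05, slope = 0.1, eps = 1e-8) {
  stopifnot(cap > 0, slope >= 0, eps > 0)
  structure(list(cap = cap, slope = slope, eps = eps),
            class = "noise_config")
}

#' Adaptive noise scale of a batch
#'
#' `min(cap, slope * mean(|X|) + eps)` over all entries of the batch
#' tensor. The result is always in `(0, cap]`.
#'
#' @param x numeric array/matrix (any shape).
#' @param cfg a [noise_config()].
#' @return scalar noise standard deviation.
#' @export
#' @examples
#' compute_noise_scale(array(0, c(2, 3, 5)))        # eps floor
#' compute_noise_scale(matrix(1, 2, 5))             # cap saturates: 0.05
compute_noise_scale <- function(x, cfg = noise_config()) {
  stopifnot(all(is.finite(x)))
  min(cfg$cap, cfg$slope * mean(abs(x)) + cfg$eps)
}

#' Noise-enhanced (NERM) view of a batch
#'
#' Adds i.i.d. Gaussian noise scaled by [compute_noise_scale()] to every
#' entry. Draws come from R's global RNG; call `set.seed()` beforehand for
#' a reproducible view.
#'
#' @param x numeric array `[B, C, F]` (any numeric array works).
#' @param cfg a [noise_config()].
#' @return array of the same shape.
#' @export
nerm_view <- function(x, cfg = noise_config()) {
  s <- compute_noise_scale(x, cfg)
  x + array(rnorm(length(x)), dim = dim(x) %||% length(x)) * s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
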