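#' Wavelet view configuration
#'
#' The wavelet-transform representation modelling (WTRM) view decomposes
#' each channel's 5-band DE profile with a single-level Haar (db1)
#' transform. Five is odd, so the profile is padded to length 6 by
#' repeating the last (gamma) value before analysis and the synthesis
#' output is truncated back to 5 — with Haar this pad-then-truncate
#' scheme round-trips exactly.
#'
#' @param basis wavelet basis; only `"haar"` (identically db1) is
#'   meaningful at signal length 5.
#' @param level decomposition level; fixed at 1.
#' @return list of class `wavelet_config`.
#' @export
wavelet_config <- function(basis = "haar", level = 1L) {
  basis <- match.arg(basis, "haar")
  if (level != 1L) stop("only level-1 decomposition is supported at F = 5",
                        call. = FALSE)
  structure(list(basis = basis, level = 1L), class = "wavelet_config")
}

#' Coefficient-mask configuration
#'
#' Probabilities of the three independent Bernoulli masks used to perturb
#' wavelet coefficients: approximation perturbation (`mu/2`), detail
#' suppression (`mu`), detail enhancement (`mu/2`). Where a suppress and
#' an enhance mask would both fire on the same cell, suppression wins.
#' `amp_a` is the amplitude of the multiplicative approximation
#' perturbation (default equal to `mu`).
#'
#' `eq6_literal = TRUE` selects the literal detail-coefficient update in
#' which cells hit by neither mask are zeroed rather than passed through;
#' the default piecewise form (x0.5 suppress, x(1 + eps * sigma) enhance,
#' x1 elsewhere) keeps `mu -> 0` an identity map.
#'
#' @param mu base mask probability (default 0.05).
#' @param amp_a approximation perturbation amplitude (default `mu`).
#' @param eq6_literal use the literal zeroing form (default `FALSE`).
#' @return list of class `mask_config`.
#' @export
mask_config <- function(mu = 0.05, amp_a = mu, eq6_literal = FALSE) {
  stopifnot(mu >= 0, mu <= 1, amp_a >= 0)
  structure(list(mu = mu, p_a = mu * 0.5, p_suppress = mu,
                 p_enhance = mu * 0.5, amp_a = amp_a,
                 eq6_literal = isTRUE(eq6_literal)),
            class = "mask_config")
}

# Haar analysis/synthesis constants for the padded length-6 signal.
.SQRT2 <- sqrt(2)

#' Level-1 Haar analysis of a 5-band profile
#'
#' Pads `x` to length 6 by repeating the last element, then applies the
#' orthonormal Haar filter pair: `cA_k = (x_{2k} + x_{2k+1}) / sqrt(2)`,
#' `cD_k = (x_{2k} - x_{2k+1}) / sqrt(2)` for the three adjacent pairs.
#'
#' @param x numeric vector of length 5 (delta..gamma DE values of one
#'   channel).
#' @param cfg a [wavelet_config()].
#' @return list with `cA` and `cD`, each length 3.
#' @seealso [haar_idwt1()] for the exact inverse.
#' @export
#' @examples
#' haar_dwt1(rep(1, 5))   # cA = sqrt(2) each, cD = 0
haar_dwt1 <- function(x, cfg = wavelet_config()) {
  if (length(x) != 5L) stop("band profile must have length 5", call. = FALSE)
  x6 <- c(x, x[5])
  ev <- x6[c(1, 3, 5)]
  od <- x6[c(2, 4, 6)]
  list(cA = (ev + od) / .SQRT2, cD = (ev - od) / .SQRT2)
}

#' Level-1 Haar synthesis back to a 5-band profile
#'
#' Inverse of [haar_dwt1()]: reconstructs the padded length-6 signal and
#' truncates to the first 5 entries.
#'
#' @param cA,cD numeric vectors of length 3.
#' @param cfg a [wavelet_config()].
#' @return numeric vector of length 5.
#' @export
haar_idwt1 <- function(cA, cD, cfg = wavelet_config()) {
  if (length(cA) != 3L || length(cD) != 3L) {
    stop("coefficient vectors must have length 3", call. = FALSE)
  }
  y <- numeric(6)
  y[c(1, 3, 5)] <- (cA + cD) / .SQRT2
  y[c(2, 4, 6)] <- (cA - cD) / .SQRT2
  y[1:5]
}

# Vectorised analysis over an [B, C, 5] array -> list of [B, C, 3] arrays.
haar_dwt_array <- function(x) {
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == 5L)
  x6 <- array(0, dim = c(dim(x)[1], dim(x)[2], 6))
  x6[, , 1:5] <- x
  x6[, , 6] <- x[, , 5]
  ev <- x6[, , c(1, 3, 5), drop = FALSE]
  od <- x6[, , c(2, 4, 6), drop = FALSE]
  list(cA = (ev + od) / .SQRT2, cD = (ev - od) / .SQRT2)
}

haar_idwt_array <- function(cA, cD) {
  d <- dim(cA)
  y <- array(0, dim = c(d[1], d[2], 6))
  y[, , c(1, 3, 5)] <- (cA + cD) / .SQRT2
  y[, , c(2, 4, 6)] <- (cA - cD) / .SQRT2
  y[, , 1:5, drop = FALSE]
}

#' Draw the three coefficient masks
#'
#' Independent Bernoulli fields with probabilities `mu/2` (approximation),
#' `mu` (suppress) and `mu/2` (enhance); an enhance bit is cleared
#' wherever the suppress mask also fired, so the two detail branches are
#' mutually exclusive. Uses the global RNG.
#'
#' @param dims integer vector giving the coefficient array shape.
#' @param cfg a [mask_config()].
#' @return list of 0/1 arrays `m_a`, `m_suppress`, `m_enhance`.
#' @export
sample_masks <- function(dims, cfg = mask_config()) {
  n <- prod(dims)
  m_a <- array(as.numeric(runif(n) < cfg$p_a), dim = dims)
  m_s <- array(as.numeric(runif(n) < cfg$p_suppress), dim = dims)
  m_e <- array(as.numeric(runif(n) < cfg$p_enhance), dim = dims)
  m_e <- m_e * (1 - m_s)   # suppression wins on collisions
  list(m_a = m_a, m_suppress = m_s, m_enhance = m_e)
}

#' Apply mask-driven perturbations to Haar coefficients
#'
#' Approximation coefficients are scaled by `1 + amp_a * M_A * eps_A`
#' (multiplicative jitter on masked cells only). Detail coefficients get a
#' piecewise multiplier: 0.5 on suppressed cells, `1 + eps_D * sigma_D` on
#' enhanced cells, 1 elsewhere (or, under `eq6_literal`, the literal form
#' `0.5 * M_suppress + M_enhance * (1 + eps_D * sigma_D)` which zeroes
#' unmasked cells).
#'
#' @param cA,cD coefficient arrays.
#' @param masks list from [sample_masks()] with shapes matching `cA`/`cD`.
#' @param draws list with standard-normal arrays `eps_a` (shape of `cA`),
#'   `eps_d` (shape of `cD`) and `sigma_d` (broadcastable to `cD`; the
#'   per-channel spread of the detail coefficients).
#' @param cfg a [mask_config()].
#' @return list with perturbed `cA`, `cD`.
#' @export
perturb_coeffs <- function(cA, cD, masks, draws, cfg = mask_config()) {
  cA2 <- cA * (1 + cfg$amp_a * masks$m_a * draws$eps_a)
  enh <- 1 + draws$eps_d * draws$sigma_d
  mult <- if (cfg$eq6_literal) {
    0.5 * masks$m_suppress + masks$m_enhance * enh
  } else {
    1 - 0.5 * masks$m_suppress + masks$m_enhance * (enh - 1)
  }
  list(cA = cA2, cD = cD * mult)
}

#' Wavelet-perturbation (WTRM) view of a batch
#'
#' Per sample and channel: Haar-analyse the 5-band profile, perturb the
#' coefficients under random masks, and synthesise back. `sigma_D` is the
#' population standard deviation of the three detail coefficients of that
#' sample-channel, so the enhancement jitter adapts to how much inter-band
#' variation the channel actually has (a flat profile is left untouched).
#' With `mu = 0` the view is the identity map up to floating-point error.
#'
#' @param x numeric array `[B, C, 5]`.
#' @param wcfg a [wavelet_config()].
#' @param mcfg a [mask_config()].
#' @return array of the same shape.
#' @export
wtrm_view <- function(x, wcfg = wavelet_config(), mcfg = mask_config()) {
  co <- haar_dwt_array(x)
  dims <- dim(co$cA)
  masks <- sample_masks(dims, mcfg)
  # population sd of the 3 detail coefficients per sample-channel
  mu_d <- (co$cD[, , 1] + co$cD[, , 2] + co$cD[, , 3]) / 3
  sig <- sqrt(((co$cD[, , 1] - mu_d)^2 + (co$cD[, , 2] - mu_d)^2 +
                 (co$cD[, , 3] - mu_d)^2) / 3)
  draws <- list(eps_a = array(rnorm(prod(dims)), dims),
                eps_d = array(rnorm(prod(dims)), dims),
                sigma_d = array(sig, dims))
  pert <- perturb_coeffs(co$cA, co$cD, masks, draws, mcfg)
  haar_idwt_array(pert$cA, pert$cD)
}
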