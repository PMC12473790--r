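#' Initialise multi-head attention parameters
#'
#' Full-width query/key/value/output projections `[d_model x d_model]`;
#' heads are contiguous `d_k = d_model / h` column slices of the projected
#' matrices. Uses the global RNG.
#'
#' @param d_model model width.
#' @param h number of heads; must divide `d_model`.
#' @return list of class `attention_params` with `W_Q`, `W_K`, `W_V`,
#'   `W_O`, `h`, `d_k`.
#' @export
attention_params <- function(d_model, h = 4L) {
  if (d_model %% h != 0) stop("d_model must be divisible by h", call. = FALSE)
  pm <- function() matrix(rnorm(d_model^2, sd = 1 / sqrt(d_model)),
                          d_model, d_model)
  structure(list(W_Q = pm(), W_K = pm(), W_V = pm(), W_O = pm(),
                 h = as.integer(h), d_k = as.integer(d_model / h)),
            class = "attention_params")
}

#' Multi-head scaled dot-product attention
#'
#' Standard transformer attention on a `[B, L, d_model]` sequence batch:
#' per head, `softmax(Q K' / sqrt(d_k)) V` on the head's `d_k`-wide slice
#' of the projections, heads concatenated and projected by `W_O`. At
#' `L = 1` the softmax over the single key is identically 1, so the
#' output reduces to `H W_V W_O` for any query/key weights.
#'
#' @param h_seq numeric array `[B, L, d_model]` (a `[B, d_model]` matrix is
#'   treated as `L = 1`).
#' @param params an [attention_params()] set.
#' @return array (or matrix, matching the input form) of the same shape.
#' @export
multi_head_attention <- function(h_seq, params) {
  was_mat <- is.matrix(h_seq)
  if (was_mat) {
    h_seq <- array(h_seq, dim = c(nrow(h_seq), 1L, ncol(h_seq)))
  }
  d <- dim(h_seq)
  dm <- d[3]
  if (dm != nrow(params$W_Q)) stop("d_model mismatch", call. = FALSE)
  b <- d[1]; l <- d[2]
  flat <- matrix(aperm(h_seq, c(2, 1, 3)), nrow = b * l, ncol = dm)
  q <- flat %*% params$W_Q
  k <- flat %*% params$W_K
  v <- flat %*% params$W_V
  out <- matrix(0, b * l, dm)
  for (hd in seq_len(params$h)) {
    cols <- (hd - 1) * params$d_k + seq_len(params$d_k)
    for (bi in seq_len(b)) {
      rows <- (bi - 1) * l + seq_len(l)
      sc <- (q[rows, cols, drop = FALSE] %*%
               t(k[rows, cols, drop = FALSE])) / sqrt(params$d_k)
      out[rows, cols] <- softmax_rows(sc) %*% v[rows, cols, drop = FALSE]
    }
  }
  res <- out %*% params$W_O
  res_arr <- aperm(array(res, dim = c(l, b, dm)), c(2, 1, 3))
  if (was_mat) matrix(res_arr, nrow = b, ncol = dm) else res_arr
}
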