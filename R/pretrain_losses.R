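# Self-supervised objective: cosine alignment between the two views of
# each sample, plus a Gram-matrix penalty that pushes different samples'
# embeddings toward orthogonality (anti-collapse).

row_norms <- function(z, eps = 1e-12) pmax(sqrt(rowSums(z * z)), eps)

#' Cross-view alignment loss
#'
#' `2 - 2 * mean_i cos(z1_i, z2_i)`: zero when the two views embed every
#' sample identically (up to positive scale), 2 for orthogonal pairs, 4
#' for anti-aligned pairs. Rows are L2-normalised with an epsilon guard
#' against zero rows.
#'
#' @param z1,z2 numeric matrices `[B, d]`, one row per sample.
#' @return scalar in `[0, 4]`.
#' @export
alignment_loss <- function(z1, z2) {
  stopifnot(all(dim(z1) == dim(z2)))
  u1 <- z1 / row_norms(z1)
  u2 <- z2 / row_norms(z2)
  2 - 2 * mean(rowSums(u1 * u2))
}

# Gradient of alignment_loss w.r.t. both inputs.
alignment_loss_grad <- function(z1, z2) {
  b <- nrow(z1)
  n1 <- row_norms(z1); n2 <- row_norms(z2)
  u1 <- z1 / n1; u2 <- z2 / n2
  cs <- rowSums(u1 * u2)
  dz1 <- -(2 / b) * (u2 - cs * u1) / n1
  dz2 <- -(2 / b) * (u1 - cs * u2) / n2
  list(dz1 = dz1, dz2 = dz2)
}

#' Gram-matrix style-diversity loss
#'
#' `||Z1 Z1' - I||_F^2 + ||Z2 Z2' - I||_F^2` over the batch Gram matrices.
#' With `normalize_rows = TRUE` (default) rows are L2-normalised first, so
#' the Gram diagonal is exactly 1 and the loss measures purely the
#' between-sample cosine overlap — driving it to zero spreads the batch
#' over orthogonal directions and prevents representation collapse.
#'
#' The value returned is the raw Frobenius quantity. `scale_by_batch`
#' divides by `B^2` and is what the pre-training objective uses so the
#' loss magnitude does not grow with batch size.
#'
#' @param z1,z2 numeric matrices `[B, d]`.
#' @param normalize_rows L2-normalise rows before the Gram product.
#' @param scale_by_batch divide by `B^2`.
#' @return non-negative scalar.
#' @export
style_diversity_loss <- function(z1, z2, normalize_rows = TRUE,
                                 scale_by_batch = FALSE) {
  one_view <- function(z) {
    if (normalize_rows) z <- z / row_norms(z)
    r <- tcrossprod(z)
    diag(r) <- diag(r) - 1
    sum(r * r)
  }
  val <- one_view(z1) + one_view(z2)
  if (scale_by_batch) val <- val / nrow(z1)^2
  val
}

style_diversity_grad <- function(z1, z2, normalize_rows = TRUE,
                                 scale_by_batch = FALSE) {
  scl <- if (scale_by_batch) 1 / nrow(z1)^2 else 1
  one_view <- function(z) {
    if (normalize_rows) {
      n <- row_norms(z)
      u <- z / n
      r <- tcrossprod(u)
      diag(r) <- diag(r) - 1
      du <- 4 * scl * (r %*% u)
      # chain through row normalisation: project out the radial component
      (du - rowSums(du * u) * u) / n
    } else {
      r <- tcrossprod(z)
      diag(r) <- diag(r) - 1
      4 * scl * (r %*% z)
    }
  }
  list(dz1 = one_view(z1), dz2 = one_view(z2))
}

#' Combined pre-training loss
#'
#' `lambda_align * L_align + lambda_style * L_style`, returning the
#' components alongside the total for logging. The style component uses
#' row normalisation and batch-size scaling as configured.
#'
#' @param z1,z2 view embeddings `[B, d]`.
#' @param cfg a [pretrain_config()].
#' @return list with `total`, `align`, `style` (the unweighted component
#'   values actually entering the sum).
#' @export
pretrain_total_loss <- function(z1, z2, cfg = pretrain_config()) {
  la <- alignment_loss(z1, z2)
  ls <- style_diversity_loss(z1, z2,
                             normalize_rows = cfg$normalize_gram,
                             scale_by_batch = cfg$normalize_gram)
  list(total = cfg$lambda_align * la + cfg$lambda_style * ls,
       align = la, style = ls)
}
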