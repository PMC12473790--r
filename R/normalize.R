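#' Per-feature z-score normalisation
#'
#' Standardises each column of a flat feature matrix to zero mean and unit
#' standard deviation, using the population (1/N) convention. When `stats`
#' is supplied (from a previous call on the fine-tuning split) its means
#' and sds are applied instead of recomputing, so the test split can be
#' normalised without leaking its own statistics.
#'
#' Columns with zero variance get their sd clamped to 1, leaving the
#' centred column all-zero; the affected columns are recorded in
#' `stats$clamped` and reported with a message.
#'
#' @param x numeric matrix `[B, D]`.
#' @param stats optional list with `mean`, `sd` (length-D vectors) from a
#'   previous call.
#' @return list with `values` (normalised matrix) and `stats`
#'   (`mean`, `sd`, `clamped` integer indices).
#' @export
#' @examples
#' z <- zscore_normalize(matrix(c(0, 2), ncol = 1))
#' z$values           # -1, 1 (population sd)
zscore_normalize <- function(x, stats = NULL) {
  x <- as.matrix(x)
  if (is.null(stats)) {
    mu <- colMeans(x)
    # population convention: sqrt(mean((x - mu)^2))
    sigma <- sqrt(colMeans(sweep(x, 2, mu)^2))
    clamped <- which(sigma == 0)
    if (length(clamped) > 0) {
      sigma[clamped] <- 1
      message(length(clamped), " zero-variance column(s); sd clamped to 1")
    }
    stats <- list(mean = mu, sd = sigma, clamped = clamped)
  } else {
    if (length(stats$mean) != ncol(x)) {
      stop("stats dimension (", length(stats$mean),
           ") does not match matrix width (", ncol(x), ")", call. = FALSE)
    }
  }
  out <- sweep(sweep(x, 2, stats$mean), 2, stats$sd, "/")
  list(values = out, stats = stats)
}
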