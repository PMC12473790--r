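#' Classification accuracy
#'
#' Fraction of samples whose predicted label equals the true label.
#'
#' @param pred,truth equal-length label vectors.
#' @return scalar in `[0, 1]`.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred and truth differ in length", call. = FALSE)
  }
  if (length(pred) == 0) stop("accuracy of an empty set is undefined",
                              call. = FALSE)
  mean(pred == truth)
}

#' Confusion matrix
#'
#' `K x K` count matrix with rows indexing the true class and columns the
#' predicted class (0-based labels); `trace / sum` equals the accuracy.
#'
#' @param pred,truth label vectors in `0..K-1`.
#' @param n_classes K.
#' @return integer matrix with dimnames `true`/`pred`.
#' @export
confusion_matrix <- function(pred, truth, n_classes) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (any(c(pred, truth) < 0L) || any(c(pred, truth) >= n_classes)) {
    stop("labels must lie in 0..K-1", call. = FALSE)
  }
  m <- matrix(0L, n_classes, n_classes,
              dimnames = list(true = 0:(n_classes - 1),
                              pred = 0:(n_classes - 1)))
  for (i in seq_along(truth)) {
    m[truth[i] + 1L, pred[i] + 1L] <- m[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  m
}

#' Aggregate per-subject accuracies
#'
#' Mean and sample (n-1) standard deviation across subjects, reported in
#' percent, the convention used for cross-corpus result tables. A single
#' subject yields sd 0 with a warning.
#'
#' @param acc numeric vector of per-subject accuracies in `[0, 1]`.
#' @return tibble with `mean_pct`, `sd_pct`, `n_subjects`.
#' @export
#' @examples
#' aggregate_subjects(c(0.8, 0.6))   # 70.00 +- 14.14
aggregate_subjects <- function(acc) {
  if (length(acc) == 0) stop("no subjects", call. = FALSE)
  s <- if (length(acc) == 1L) {
    warning("single subject: sd reported as 0")
    0
  } else {
    sd(acc)
  }
  tibble::tibble(mean_pct = 100 * mean(acc), sd_pct = 100 * s,
                 n_subjects = length(acc))
}
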