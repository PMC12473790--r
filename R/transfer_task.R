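# Target-side trial splits printed for the six supported cross-corpus
# tasks: trials used for fine-tuning vs held out for testing, per
# subject-session of the *target* corpus.
.task_splits <- list(
  "SEED"     = c(finetune = 9L,  test = 6L),
  "SEED-IV3" = c(finetune = 12L, test = 6L),
  "SEED-V3"  = c(finetune = 6L,  test = 3L),
  "SEED-IV4" = c(finetune = 16L, test = 8L),
  "SEED-V4"  = c(finetune = 8L,  test = 4L)
)

.supported_pairs <- list(
  c("SEED", "SEED-IV3"), c("SEED-IV3", "SEED"),
  c("SEED", "SEED-V3"),  c("SEED-V3", "SEED"),
  c("SEED-IV4", "SEED-V4"), c("SEED-V4", "SEED-IV4")
)

#' Define a cross-corpus transfer task
#'
#' A transfer task names a source corpus (used for pre-training only) and a
#' target corpus whose trials are partitioned, per subject-session, into a
#' fine-tuning set and a disjoint test set. The six supported named pairs
#' reproduce the published protocol splits: SEED 9/6, SEED-IV (3-class)
#' 12/6, SEED-V (3-class subset) 6/3, SEED-IV (4-class) 16/8, SEED-V
#' (4-class subset) 8/4. Synthetic corpora may be paired by passing
#' explicit counts.
#'
#' By default the first `n_finetune` trial ids (0-based) go to the
#' fine-tune set and the following `n_test` to the test set; pass
#' `finetune_trials`/`test_trials` to override.
#'
#' @param source,target corpus names. Known names: `"SEED"`, `"SEED-IV3"`,
#'   `"SEED-V3"`, `"SEED-IV4"`, `"SEED-V4"`; anything else requires
#'   explicit counts.
#' @param n_finetune,n_test trial counts for unknown (synthetic) targets.
#' @param n_classes number of emotion classes; inferred from the target
#'   name when known (3 or 4).
#' @param finetune_trials,test_trials optional explicit 0-based trial id
#'   sets (must be disjoint).
#' @return An object of class `transfer_task`: list with `source`,
#'   `target`, `n_classes`, `finetune_trials`, `test_trials`.
#' @export
#' @examples
#' make_transfer_task("SEED", "SEED-IV3")
#' make_transfer_task("synthA", "synthB", n_finetune = 9, n_test = 6,
#'                    n_classes = 3)
make_transfer_task <- function(source, target,
                               n_finetune = NULL, n_test = NULL,
                               n_classes = NULL,
                               finetune_trials = NULL, test_trials = NULL) {
  known <- target %in% names(.task_splits)
  if (known && is.null(n_finetune)) {
    pair_ok <- any(vapply(.supported_pairs,
                          function(p) p[1] == source && p[2] == target,
                          logical(1)))
    if (!pair_ok) {
      stop("(", source, " -> ", target, ") is not one of the six ",
           "supported tasks; pass explicit counts for a custom pair",
           call. = FALSE)
    }
    n_finetune <- .task_splits[[target]][["finetune"]]
    n_test     <- .task_splits[[target]][["test"]]
  }
  if (is.null(n_finetune) || is.null(n_test)) {
    stop("unknown target corpus '", target,
         "': supply n_finetune and n_test", call. = FALSE)
  }
  if (is.null(n_classes)) {
    n_classes <- if (known) {
      if (grepl("4$", target)) 4L else 3L
    } else {
      stop("supply n_classes for a custom pair", call. = FALSE)
    }
  }
  if (is.null(finetune_trials)) {
    finetune_trials <- seq_len(n_finetune) - 1L
  }
  if (is.null(test_trials)) {
    test_trials <- n_finetune + seq_len(n_test) - 1L
  }
  finetune_trials <- as.integer(finetune_trials)
  test_trials <- as.integer(test_trials)
  if (length(intersect(finetune_trials, test_trials)) > 0) {
    stop("fine-tune and test trial sets overlap", call. = FALSE)
  }
  if (length(finetune_trials) != n_finetune ||
      length(test_trials) != n_test) {
    stop("trial id sets do not match the declared counts", call. = FALSE)
  }
  structure(
    list(source = source, target = target, n_classes = as.integer(n_classes),
         finetune_trials = finetune_trials, test_trials = test_trials),
    class = "transfer_task")
}

#' @export
print.transfer_task <- function(x, ...) {
  cat(sprintf("<transfer_task> %s -> %s (%d classes)\n",
              x$source, x$target, x$n_classes))
  cat(sprintf("  target fine-tune trials: %s\n",
              paste(x$finetune_trials, collapse = " ")))
  cat(sprintf("  target test trials:      %s\n",
              paste(x$test_trials, collapse = " ")))
  invisible(x)
}
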