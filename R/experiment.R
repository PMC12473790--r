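#' Run a full cross-corpus transfer experiment
#'
#' End-to-end protocol on a synthetic (or user-supplied) corpus pair:
#'
#' 1. generate the source and target corpora and the trial split;
#' 2. stage 1 — self-supervised pre-training of the shared extractor on
#'    the unlabelled union of the source corpus and the target fine-tune
#'    split (z-scored with that union's statistics);
#' 3. stage 2 — supervised fine-tuning of the dual-encoder model on the
#'    labelled target fine-tune trials (z-scored with the fine-tune
#'    split's statistics, reused on the test split);
#' 4. evaluation on the held-out target test trials, per subject.
#'
#' The `variant` argument reproduces the ablation rows: `"no-nerm"` and
#' `"no-wtrm"` replace the removed view by the identity view during
#' pre-training; `"no-pretrain"` skips stage 1 and initialises the
#' encoders randomly. Everything downstream of the variant switch is
#' identical, and the whole run is deterministic given `seed`.
#'
#' The default model/schedule profile (`d_model = 64`, 60 pre-training
#' epochs, learning rate 1e-3 in both stages) is sized for the default
#' synthetic corpora; pass explicit configs to change it.
#'
#' @param variant one of `"full"`, `"no-nerm"`, `"no-wtrm"`,
#'   `"no-pretrain"`.
#' @param cfg_src source-corpus [synth_config()]; its `seed` is combined
#'   with `seed`.
#' @param cfg_tgt target-corpus config (default: [shifted_target_config()]
#'   of `cfg_src`).
#' @param pre_cfg a [pretrain_config()].
#' @param ft_cfg a [finetune_config()].
#' @param n_finetune,n_test target trial split (defaults 9/6).
#' @param h,d_hidden,dropout model head settings.
#' @param seed master seed; offsets the corpus and stage seeds.
#' @return object of class `cate_eval_report`: list with `variant`,
#'   `accuracy` (overall test accuracy), `per_subject` (tibble),
#'   `summary` (tibble from [aggregate_subjects()]), `confusion`,
#'   `task`, `history` (list of stage histories), `seed`.
#' @export
run_experiment <- function(variant = c("full", "no-nerm", "no-wtrm",
                                       "no-pretrain"),
                           cfg_src = synth_config(),
                           cfg_tgt = shifted_target_config(cfg_src),
                           pre_cfg = pretrain_config(epochs = 60L,
                                                     d_model = 64L),
                           ft_cfg = finetune_config(learning_rate = 1e-3),
                           n_finetune = 9L, n_test = 6L,
                           h = 4L, d_hidden = 64L, dropout = 0.1,
                           seed = 1L) {
  variant <- match.arg(variant)
  seed <- as.integer(seed)
  cfg_src$seed <- cfg_src$seed + seed * 101L
  cfg_tgt$seed <- cfg_tgt$seed + seed * 101L
  pair <- generate_transfer_pair(cfg_src, cfg_tgt,
                                 n_finetune = n_finetune, n_test = n_test)
  task <- pair$task
  ft_idx <- pair$target$trial %in% task$finetune_trials
  te_idx <- pair$target$trial %in% task$test_trials
  tgt_ft <- fs_subset(pair$target, ft_idx)
  tgt_te <- fs_subset(pair$target, te_idx)

  pre <- NULL
  if (variant != "no-pretrain") {
    x_pre <- rbind(de_flatten(pair$source), de_flatten(tgt_ft))
    z_pre <- zscore_normalize(x_pre)
    views <- switch(variant,
                    full = c("nerm", "wtrm"),
                    `no-nerm` = c("identity", "wtrm"),
                    `no-wtrm` = c("nerm", "identity"))
    pre_cfg$seed <- pre_cfg$seed + seed
    pre <- run_pretraining(z_pre$values, cfg = pre_cfg, views = views)
  }

  z_ft <- zscore_normalize(de_flatten(tgt_ft))
  x_te <- zscore_normalize(de_flatten(tgt_te), stats = z_ft$stats)$values

  set.seed(seed + 7L)
  model <- dual_encoder_init(
    n_classes = task$n_classes,
    pretrained = if (is.null(pre)) NULL else pre$params,
    d_input = ncol(z_ft$values), d_model = pre_cfg$d_model,
    h = h, d_hidden = d_hidden, dropout = dropout)
  ft_cfg$seed <- ft_cfg$seed + seed
  ft <- run_finetuning(model, z_ft$values, tgt_ft$labels, cfg = ft_cfg)

  pred <- predict(ft$model, x_te)
  subj <- sort(unique(tgt_te$subject))
  per_subject <- tibble::tibble(
    subject = subj,
    n = vapply(subj, function(s) sum(tgt_te$subject == s), integer(1)),
    accuracy = vapply(subj, function(s) {
      i <- tgt_te$subject == s
      accuracy(pred[i], tgt_te$labels[i])
    }, numeric(1)))
  structure(
    list(variant = variant,
         accuracy = accuracy(pred, tgt_te$labels),
         per_subject = per_subject,
         summary = aggregate_subjects(per_subject$accuracy),
         confusion = confusion_matrix(pred, tgt_te$labels, task$n_classes),
         task = task,
         history = list(pretrain = if (is.null(pre)) NULL else pre$history,
                        finetune = ft$history),
         seed = seed),
    class = "cate_eval_report")
}

#' @export
print.cate_eval_report <- function(x, ...) {
  cat(sprintf(
    "<cate_eval_report> variant %s | target test accuracy %.2f%% (%.2f +- %.2f%% across %d subjects)\n",
    x$variant, 100 * x$accuracy, x$summary$mean_pct, x$summary$sd_pct,
    x$summary$n_subjects))
  invisible(x)
}

#' Tidy a transfer-experiment report
#'
#' One row per target subject with its test accuracy.
#'
#' @param x a `cate_eval_report` from [run_experiment()].
#' @param ... unused.
#' @return tibble with `variant`, `subject`, `n`, `accuracy`.
#' @export
tidy.cate_eval_report <- function(x, ...) {
  dplyr::mutate(x$per_subject, variant = x$variant, .before = 1)
}

#' One-row summary of a transfer-experiment report
#'
#' @param x a `cate_eval_report`.
#' @param ... unused.
#' @return tibble with `variant`, `accuracy`, `mean_pct`, `sd_pct`,
#'   `n_subjects`, `seed`.
#' @export
glance.cate_eval_report <- function(x, ...) {
  tibble::tibble(variant = x$variant, accuracy = x$accuracy,
                 mean_pct = x$summary$mean_pct, sd_pct = x$summary$sd_pct,
                 n_subjects = x$summary$n_subjects, seed = x$seed)
}

#' Plot the confusion matrix of a report
#'
#' Heat-map of the test-set confusion matrix with counts annotated.
#'
#' @param object a `cate_eval_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cate_eval_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "pred", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("Target test confusion (%s, %.1f%%)",
                                  object$variant, 100 * object$accuracy),
                  x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Loss (and accuracy, if present) per epoch for pre-training or
#' fine-tuning histories.
#'
#' @param object a `cate_pretrain` or `cate_finetune` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cate_pretrain <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "component",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Self-supervised pre-training",
                  y = "loss") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cate_pretrain
#' @export
autoplot.cate_finetune <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history,
                              c("loss", "accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = "Supervised fine-tuning") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
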