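#' Default synthetic class-conditional band means
#'
#' A synthetic (not dataset-derived) table of mean differential-entropy
#' values per emotion class and band, in log-power units on the typical
#' DE scale. The emotional signal lives where affective EEG studies
#' usually report it: the positive class has elevated beta/gamma power,
#' the neutral class elevated alpha, the negative class a flatter
#' high-frequency profile; delta/theta carry little class information.
#' Rows beyond the third (for 4- or 5-class corpora) interpolate between
#' these archetypes.
#'
#' @param n_classes number of classes K (2..5).
#' @return numeric matrix `[K, 5]` with band columns delta..gamma.
#' @export
default_class_band_means <- function(n_classes = 3L) {
  base <- rbind(
    negative = c(2.0, 1.8, 1.5, 1.2, 0.9),
    neutral  = c(2.0, 1.7, 1.9, 1.0, 0.7),
    positive = c(1.9, 1.7, 1.4, 1.6, 1.3),
    fear     = c(2.1, 1.9, 1.3, 1.4, 1.1),
    sad      = c(2.2, 1.8, 1.6, 1.1, 0.8))
  colnames(base) <- CATE_BANDS
  stopifnot(n_classes >= 2, n_classes <= nrow(base))
  base[seq_len(n_classes), , drop = FALSE]
}

#' Deterministic class-signal topography
#'
#' Spatial expression profile of the emotion signal: channel c carries
#' the class-conditional band deviation with gain
#' `1 + 0.75 * cos(2 * pi * c / C)` (mean 1 over channels). Emotion
#' effects in EEG are not spatially uniform — they peak at specific
#' sites — and this smooth fixed pattern gives the class signal a
#' channel structure orthogonal to spatially uniform amplitude drift.
#' It models physiology, not hardware, so both corpora of a transfer
#' pair share it.
#'
#' @param n_channels number of channels C.
#' @return numeric vector of length C.
#' @export
default_class_topography <- function(n_channels = 62L) {
  1 + 0.75 * cos(2 * pi * (seq_len(n_channels) - 1L) / n_channels)
}

#' Synthetic corpus configuration
#'
#' Describes one synthetic DE corpus. A sample of class k, subject s,
#' channel c, band f is generated as
#' `gain_f * (mean_f + topo_c * dev[k, f] + subject_offset_s +
#'  channel_offset_c + drift) + offset_f + N(0, noise_sd)`,
#' where `mean_f` is the across-class mean of band f, `dev[k, f]` the
#' class-conditional deviation from it (from `class_band_means`) and
#' `topo_c` the class-signal topography,
#' with subject offsets ~ `N(0, subject_sd)` and fixed per-corpus channel
#' offsets ~ `N(0, channel_sd)`. The per-band `corpus_gain`/
#' `corpus_offset` pair is the controllable affine domain shift between
#' corpora; `noise_sd` models independent per-feature variability, while
#' `band_noise_sd` adds a per-sample fluctuation shared by all channels
#' of a band — the spatially correlated broadband amplitude drift
#' (arousal/vigilance effects) that makes real DE features far less
#' separable than channel-independent noise would suggest, since it
#' masks the class signal in exactly the directions that carry it.
#' Trial labels are assigned round-robin over the classes, and samples
#' of one trial form one contiguous block.
#'
#' @param n_subjects subjects in the corpus (default 3).
#' @param n_trials_per_subject trials per subject (default 15; must be
#'   >= `n_classes` so every class occurs).
#' @param samples_per_trial contiguous samples per trial (default 15).
#' @param n_classes number of emotion classes K (default 3).
#' @param n_channels channels C (default 62).
#' @param class_band_means `[K, 5]` matrix of class-conditional band
#'   means (default [default_class_band_means()]).
#' @param class_topography length-C channel gain on the class deviation
#'   (default [default_class_topography()]; shared across a transfer
#'   pair).
#' @param subject_sd sd of per-subject offsets (default 0.2).
#' @param channel_sd sd of the fixed per-channel offsets (default 0.3).
#' @param corpus_gain,corpus_offset length-5 per-band affine shift
#'   (defaults: identity).
#' @param noise_sd independent per-feature noise sd (default 0.4).
#' @param band_noise_sd sd of the per-sample, per-band fluctuation shared
#'   across channels (default 0.5).
#' @param seed corpus RNG seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 3L, n_trials_per_subject = 15L,
                         samples_per_trial = 15L, n_classes = 3L,
                         n_channels = 62L,
                         class_band_means =
                           default_class_band_means(n_classes),
                         class_topography =
                           default_class_topography(n_channels),
                         subject_sd = 0.2, channel_sd = 0.3,
                         corpus_gain = rep(1, 5),
                         corpus_offset = rep(0, 5),
                         noise_sd = 0.4, band_noise_sd = 0.5,
                         seed = 1L) {
  stopifnot(n_classes >= 2, n_trials_per_subject >= n_classes,
            subject_sd >= 0, channel_sd >= 0, noise_sd >= 0,
            band_noise_sd >= 0,
            nrow(class_band_means) == n_classes,
            ncol(class_band_means) == 5L,
            length(class_topography) == n_channels,
            length(corpus_gain) == 5L, length(corpus_offset) == 5L)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials_per_subject = as.integer(n_trials_per_subject),
                 samples_per_trial = as.integer(samples_per_trial),
                 n_classes = as.integer(n_classes),
                 n_channels = as.integer(n_channels),
                 class_band_means = class_band_means,
                 class_topography = class_topography,
                 subject_sd = subject_sd, channel_sd = channel_sd,
                 corpus_gain = corpus_gain, corpus_offset = corpus_offset,
                 noise_sd = noise_sd, band_noise_sd = band_noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic DE corpus
#'
#' Draws a full corpus under the model described in [synth_config()].
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return a [de_feature_set] with
#'   `n_subjects * n_trials_per_subject * samples_per_trial` samples.
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  ns <- cfg$n_subjects; nt <- cfg$n_trials_per_subject
  sp <- cfg$samples_per_trial; cc <- cfg$n_channels
  n <- ns * nt * sp
  chan_off <- rnorm(cc, sd = cfg$channel_sd)
  subj_off <- rnorm(ns, sd = cfg$subject_sd)
  subject <- rep(seq_len(ns) - 1L, each = nt * sp)
  trial <- rep(rep(seq_len(nt) - 1L, each = sp), times = ns)
  labels <- trial %% cfg$n_classes
  vals <- array(0, dim = c(n, cc, 5))
  # class deviation around the across-class band mean carries the
  # topography; subject offset, channel offset and the shared band drift
  # are spatially uniform additions; affine band shift applied last
  m_overall <- colMeans(cfg$class_band_means)
  dev <- sweep(cfg$class_band_means, 2, m_overall)
  band_drift <- matrix(rnorm(n * 5, sd = cfg$band_noise_sd), n, 5)
  for (f in 1:5) {
    base <- m_overall[f] + subj_off[subject + 1L] + band_drift[, f]
    m <- outer(base, chan_off, "+") +
      outer(dev[labels + 1L, f], cfg$class_topography)
    vals[, , f] <- cfg$corpus_gain[f] * m + cfg$corpus_offset[f]
  }
  vals <- vals + array(rnorm(length(vals), sd = cfg$noise_sd), dim(vals))
  de_feature_set(vals, labels = labels, subject = subject,
                 session = 0L, trial = trial)
}

#' Generate a synthetic source/target transfer pair
#'
#' Two corpora sharing the same class-conditional band structure but
#' differing by the per-band affine transform and noise level of their
#' configs (the domain shift), plus a [make_transfer_task()] splitting
#' the target trials into fine-tune and test sets.
#'
#' @param cfg_src,cfg_tgt [synth_config()]s with identical `n_classes`,
#'   `n_channels` and `class_band_means`; give them different seeds and
#'   shift parameters.
#' @param n_finetune,n_test target trial split counts (defaults 9/6,
#'   mirroring the 15-trial protocol).
#' @return list with `source`, `target` ([de_feature_set]s) and `task`.
#' @export
generate_transfer_pair <- function(cfg_src, cfg_tgt,
                                   n_finetune = 9L, n_test = 6L) {
  if (cfg_src$n_classes != cfg_tgt$n_classes) {
    stop("source and target must have the same number of classes",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(cfg_src$class_band_means,
                        cfg_tgt$class_band_means)) ||
      !isTRUE(all.equal(cfg_src$class_topography,
                        cfg_tgt$class_topography))) {
    stop("source and target must share class_band_means and topography",
         call. = FALSE)
  }
  if (n_finetune + n_test > cfg_tgt$n_trials_per_subject) {
    stop("split exceeds target trials per subject", call. = FALSE)
  }
  task <- make_transfer_task("synth-source", "synth-target",
                             n_finetune = n_finetune, n_test = n_test,
                             n_classes = cfg_src$n_classes)
  list(source = generate_corpus(cfg_src),
       target = generate_corpus(cfg_tgt),
       task = task)
}

#' Default shifted target configuration
#'
#' Companion to [synth_config()]: same class structure, but a fixed
#' band-wise affine distortion (gains 0.75–1.3, offsets up to +-0.4) and
#' a higher noise floor, emulating a corpus recorded with different
#' hardware and protocol.
#'
#' @param base a [synth_config()] describing the source corpus.
#' @param seed target corpus seed (default `base$seed + 1000`).
#' @return a [synth_config()] for the target corpus.
#' @export
shifted_target_config <- function(base, seed = base$seed + 1000L) {
  cfg <- base
  cfg$corpus_gain <- c(1.30, 0.80, 1.20, 0.75, 1.25)
  cfg$corpus_offset <- c(0.40, -0.30, 0.20, -0.20, 0.30)
  cfg$noise_sd <- base$noise_sd * 1.25
  cfg$seed <- as.integer(seed)
  cfg
}
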