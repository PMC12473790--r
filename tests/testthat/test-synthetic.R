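test_that("the noiseless limit reproduces the class band means exactly", {
  cfg <- synth_config(n_subjects = 2L, n_trials_per_subject = 3L,
                      samples_per_trial = 2L, n_channels = 4L,
                      class_topography = rep(1, 4),
                      subject_sd = 0, channel_sd = 0, noise_sd = 0,
                      band_noise_sd = 0, seed = 1L)
  fs <- generate_corpus(cfg)
  for (k in 0:2) for (f in 1:5) {
    vals <- fs$values[fs$labels == k, , f]
    expect_equal(unname(vals), array(cfg$class_band_means[k + 1, f],
                                     dim(vals)))
  }
})

test_that("corpus structure matches the configuration exactly", {
  cfg <- tiny_synth()
  fs <- generate_corpus(cfg)
  expect_identical(dim(fs)[1], 2L * 6L * 5L)
  expect_identical(dim(fs)[2:3], c(8L, 5L))
  # round-robin trial labels, single label per trial, contiguous blocks
  expect_identical(fs$labels, fs$trial %% 3L)
  expect_identical(fs$trial[1:10], rep(0:1, each = 5L))
  # seed determinism
  expect_identical(generate_corpus(cfg)$values, fs$values)
})

test_that("empirical class-band means converge to the configured means", {
  cfg <- synth_config(n_subjects = 1L, n_trials_per_subject = 99L,
                      samples_per_trial = 35L, n_channels = 62L,
                      class_topography = rep(1, 62),
                      subject_sd = 0, channel_sd = 0, seed = 3L)
  fs <- generate_corpus(cfg)   # 3465 samples, ~1155 per class
  for (k in 0:2) {
    idx <- fs$labels == k
    nk <- sum(idx)
    for (f in 1:5) {
      emp <- mean(fs$values[idx, , f])
      # shared band drift does not average over channels; feature noise does
      se <- sqrt(cfg$band_noise_sd^2 / nk +
                   cfg$noise_sd^2 / (nk * cfg$n_channels))
      expect_lt(abs(emp - cfg$class_band_means[k + 1, f]), 3 * se)
    }
  }
})

test_that("a transfer pair without shift differs only by sampling noise", {
  cfg_a <- tiny_synth(seed = 1L)
  cfg_b <- tiny_synth(seed = 2L)
  pair <- generate_transfer_pair(cfg_a, cfg_b, n_finetune = 4L, n_test = 2L)
  expect_length(intersect(pair$task$finetune_trials,
                          pair$task$test_trials), 0L)
  for (f in 1:5) {
    ma <- mean(pair$source$values[, , f])
    mb <- mean(pair$target$values[, , f])
    n <- dim(pair$source)[1]
    se <- sqrt(2) * sqrt(cfg_a$band_noise_sd^2 / n +
                           (cfg_a$subject_sd^2) / cfg_a$n_subjects +
                           (cfg_a$channel_sd^2) / cfg_a$n_channels +
                           cfg_a$noise_sd^2 / (n * cfg_a$n_channels))
    expect_lt(abs(ma - mb), 3 * se)
  }
  expect_error(generate_transfer_pair(cfg_a, tiny_synth(n_classes = 4L)),
               "same number of classes")
})

test_that("the affine band shift moves corpus means as configured", {
  base <- synth_config(n_subjects = 2L, n_trials_per_subject = 6L,
                       samples_per_trial = 40L, n_channels = 20L,
                       subject_sd = 0, channel_sd = 0, seed = 5L)
  shifted <- shifted_target_config(base, seed = 6L)
  fs0 <- generate_corpus(base)
  fs1 <- generate_corpus(shifted)
  for (f in 1:5) {
    m0_theory <- mean(base$class_band_means[, f])
    m1_theory <- shifted$corpus_gain[f] * m0_theory +
      shifted$corpus_offset[f]
    expect_equal(mean(fs1$values[, , f]), m1_theory, tolerance = 0.12)
    expect_equal(mean(fs0$values[, , f]), m0_theory, tolerance = 0.12)
  }
})

test_that("the domain shift degrades an unadapted source classifier", {
  gap <- vapply(1:5, function(s) {
    cfg_s <- synth_config(seed = s)
    cfg_t <- shifted_target_config(cfg_s, seed = s + 100L)
    pair <- generate_transfer_pair(cfg_s, cfg_t)
    xs <- de_flatten(pair$source); xt <- de_flatten(pair$target)
    fit <- nearest_centroid_fit(xs, pair$source$labels)
    acc_src <- mean(nearest_centroid_predict(fit, xs) ==
                      pair$source$labels)
    acc_tgt <- mean(nearest_centroid_predict(fit, xt) ==
                      pair$target$labels)
    acc_src - acc_tgt
  }, numeric(1))
  expect_gt(mean(gap), 0)
})
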