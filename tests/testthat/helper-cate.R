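# Central finite-difference gradient of a scalar function of a vector.
numgrad <- function(f, p, h = 1e-6) {
  g <- p
  for (i in seq_along(p)) {
    p1 <- p; p1[i] <- p1[i] + h
    p2 <- p; p2[i] <- p2[i] - h
    g[i] <- (f(p1) - f(p2)) / (2 * h)
  }
  g
}

# Nearest-centroid classifier, used as a simple reference learner.
nearest_centroid_fit <- function(x, y) {
  t(sapply(sort(unique(y)), function(k) colMeans(x[y == k, , drop = FALSE])))
}
nearest_centroid_predict <- function(centroids, x) {
  d2 <- outer(rowSums(x^2), rowSums(centroids^2), "+") -
    2 * x %*% t(centroids)
  max.col(-d2, ties.method = "first") - 1L
}

# Tiny corpus configuration for fast structural tests.
tiny_synth <- function(seed = 1L, ...) {
  synth_config(n_subjects = 2L, n_trials_per_subject = 6L,
               samples_per_trial = 5L, n_channels = 8L, seed = seed, ...)
}
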