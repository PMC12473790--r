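test_that("flatten uses channel-major order (band index fastest)", {
  C <- 62L; F <- 5L
  x <- array(0, dim = c(1, C, F))
  for (c in 0:(C - 1)) for (f in 0:(F - 1)) x[1, c + 1, f + 1] <- 10 * c + f
  m <- de_flatten(x)
  expect_equal(dim(m), c(1L, C * F))
  # brute-force index enumeration oracle
  for (c in 0:(C - 1)) for (f in 0:(F - 1)) {
    expect_identical(m[1, c * F + f + 1], 10 * c + f)
  }
})

test_that("flatten and unflatten are mutual inverses", {
  set.seed(1)
  for (dims in list(c(1, 62, 5), c(7, 62, 5), c(4, 8, 5))) {
    x <- array(rnorm(prod(dims)), dims)
    m <- de_flatten(x)
    expect_equal(dim(m), c(dims[1], dims[2] * dims[3]))
    expect_identical(de_unflatten(m, dims[2], dims[3]), x)
    expect_identical(de_flatten(de_unflatten(m, dims[2], dims[3])), m)
  }
  expect_identical(de_flatten(array(0, c(1, 62, 5))), matrix(0, 1, 310))
})

test_that("feature-set construction validates shapes and labels", {
  v <- array(rnorm(6 * 62 * 5), c(6, 62, 5))
  fs <- de_feature_set(v, labels = rep(0:1, each = 3),
                       trial = rep(0:1, each = 3))
  expect_s3_class(fs, "de_feature_set")
  expect_identical(dim(fs), dim(v))
  # flat-matrix input is reshaped
  fs2 <- de_feature_set(de_flatten(v), labels = rep(0:1, each = 3),
                        trial = rep(0:1, each = 3))
  expect_identical(fs2$values, v)
  # label length mismatch
  expect_error(de_feature_set(v, labels = 0:1), "length")
  # one trial, two labels
  expect_error(de_feature_set(v, labels = c(0, 1, 0, 1, 0, 1)),
               "more than one label")
  # non-finite values
  v[1, 1, 1] <- NA
  expect_error(de_feature_set(v, labels = rep(0L, 6),
                              trial = rep(0:1, each = 3)), "finite")
  # width that does not factor into channels x bands
  expect_error(de_unflatten(matrix(0, 2, 300), 62, 5), "not 62 x 5")
})

test_that("csv and rds layouts round-trip bitwise", {
  set.seed(42)
  fs <- de_feature_set(array(rnorm(10 * 62 * 5), c(10, 62, 5)),
                       labels = rep(0:1, 5) * 0L + rep(c(0L, 1L), each = 5),
                       trial = rep(c(0L, 1L), each = 5))
  d <- withr::local_tempdir()
  csv_dir <- file.path(d, "corpus")
  write_feature_set(fs, csv_dir, layout = "csv")
  back <- read_feature_set(csv_dir, layout = "csv")
  expect_identical(back$values, fs$values)
  expect_identical(back$labels, fs$labels)
  expect_identical(back$trial, fs$trial)

  rds <- file.path(d, "corpus.rds")
  write_feature_set(fs, rds, layout = "rds")
  expect_identical(read_feature_set(rds, layout = "rds")$values, fs$values)

  # degenerate inputs
  expect_error(read_feature_set(file.path(d, "nope"), "csv"), "no such path")
  empty <- file.path(d, "empty")
  dir.create(empty); file.create(file.path(empty, "values.csv"))
  expect_error(read_feature_set(empty, "csv"), "empty or missing")
})

test_that("as_tibble gives one row per sample with metadata columns", {
  fs <- de_feature_set(array(rnorm(4 * 8 * 5), c(4, 8, 5)),
                       labels = rep(0L, 4), n_channels = 8L)
  tb <- tibble::as_tibble(fs)
  expect_identical(nrow(tb), 4L)
  expect_identical(ncol(tb), 5L + 40L)
  expect_named(tb[, 1:5], c("sample", "subject", "session", "trial", "label"))
})

test_that("z-score normalisation follows the population convention", {
  z <- zscore_normalize(matrix(c(0, 2), ncol = 1))
  expect_equal(z$values, matrix(c(-1, 1), ncol = 1))
  expect_equal(z$stats$mean, 1)
  expect_equal(z$stats$sd, 1)   # population: sqrt(mean((x-mu)^2)) = 1

  # constant column: clamped sd, all-zero output, recorded
  expect_message(z2 <- zscore_normalize(cbind(c(1, 1, 1), c(0, 1, 2))),
                 "clamped")
  expect_equal(z2$values[, 1], rep(0, 3))
  expect_identical(z2$stats$clamped, 1L)
  expect_equal(z2$stats$sd[1], 1)

  # train stats applied to a test row equal to the train mean -> zeros
  set.seed(1)
  xtr <- matrix(rnorm(20), 5, 4)
  ztr <- zscore_normalize(xtr)
  xte <- matrix(ztr$stats$mean, 1, 4)
  expect_equal(zscore_normalize(xte, ztr$stats)$values,
               matrix(0, 1, 4))
  # dimension check
  expect_error(zscore_normalize(matrix(0, 2, 3), ztr$stats), "match")
})
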