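test_that("extractor degeneracies and equivariance hold", {
  set.seed(1)
  p <- extractor_init(6, 4)
  x <- matrix(rnorm(18), 3, 6)
  # W1 = 0: GELU(0) = 0, LayerNorm of a constant row is 0 -> rows are b2
  p0 <- p; p0$W1[] <- 0; p0$b1[] <- 0; p0$b2 <- rnorm(4)
  z <- extract_features(x, p0)
  expect_equal(z, matrix(p0$b2, 3, 4, byrow = TRUE))
  # determinism and row-wise (permutation-equivariant) application
  expect_identical(extract_features(x, p), extract_features(x, p))
  perm <- c(3, 1, 2)
  expect_equal(extract_features(x[perm, ], p),
               extract_features(x, p)[perm, ])
  expect_error(extract_features(matrix(0, 2, 5), p), "does not match")
})

test_that("extractor backward pass matches finite differences", {
  set.seed(2)
  p <- extractor_init(4, 3)
  x <- matrix(rnorm(20), 5, 4)
  tgt <- matrix(rnorm(15), 5, 3)
  fw <- cate:::extractor_forward(x, p)
  g <- cate:::extractor_backward(2 * (fw$z - tgt), fw$cache, p)
  for (nm in c("W1", "b1", "W2", "b2")) {
    fn <- function(v) {
      q <- p; q[[nm]][] <- v
      sum((cate:::extractor_forward(x, q)$z - tgt)^2)
    }
    ng <- numgrad(fn, as.vector(p[[nm]]))
    expect_lt(max(abs(ng - as.vector(g[[nm]]))), 1e-6)
  }
})

test_that("alignment loss hits its closed-form anchor values", {
  set.seed(3)
  z <- matrix(rnorm(12), 4, 3)
  expect_equal(alignment_loss(z, z), 0)
  expect_equal(alignment_loss(z, -z), 4)
  zo <- cbind(c(1, 0), c(0, 1), 0)        # rowwise-orthogonal pair
  z2 <- cbind(c(0, 1), c(1, 0), 0)
  expect_equal(alignment_loss(zo, z2), 2)
  # range and positive-rescaling invariance
  for (i in 1:100) {
    a <- matrix(rnorm(12), 4); b <- matrix(rnorm(12), 4)
    v <- alignment_loss(a, b)
    expect_gte(v, 0); expect_lte(v, 4)
    expect_equal(alignment_loss(a * runif(4, 0.1, 9), b), v)
  }
})

test_that("style-diversity loss matches hand Frobenius computations", {
  ortho <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(style_diversity_loss(ortho, ortho), 0)
  dup <- rbind(c(1, 0, 0), c(1, 0, 0))
  # ||[[1,1],[1,1]] - I||_F^2 = 2 from the duplicated view, 0 from ortho
  expect_equal(style_diversity_loss(dup, ortho), 2)
  expect_equal(style_diversity_loss(dup, ortho, scale_by_batch = TRUE),
               2 / 4)
  set.seed(4)
  for (i in 1:200) {
    a <- matrix(rnorm(12), 4); b <- matrix(rnorm(12), 4)
    expect_gte(style_diversity_loss(a, b), 0)
  }
  # invariance under joint right-rotation (Gram matrices unchanged)
  a <- matrix(rnorm(20), 4, 5); b <- matrix(rnorm(20), 4, 5)
  q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  expect_equal(style_diversity_loss(a %*% q, b %*% q),
               style_diversity_loss(a, b))
  expect_equal(style_diversity_loss(a %*% q, b %*% q, FALSE),
               style_diversity_loss(a, b, FALSE))
})

test_that("loss gradients match finite differences", {
  set.seed(5)
  z1 <- matrix(rnorm(12), 4, 3); z2 <- matrix(rnorm(12), 4, 3)
  ga <- cate:::alignment_loss_grad(z1, z2)
  ng <- numgrad(function(v) alignment_loss(matrix(v, 4), z2), as.vector(z1))
  expect_lt(max(abs(ng - as.vector(ga$dz1))), 1e-7)
  ng2 <- numgrad(function(v) alignment_loss(z1, matrix(v, 4)), as.vector(z2))
  expect_lt(max(abs(ng2 - as.vector(ga$dz2))), 1e-7)
  for (norm in c(TRUE, FALSE)) {
    gs <- cate:::style_diversity_grad(z1, z2, norm, norm)
    ngs <- numgrad(function(v)
      style_diversity_loss(matrix(v, 4), z2, norm, norm), as.vector(z1))
    expect_lt(max(abs(ngs - as.vector(gs$dz1))), 1e-6)
  }
})

test_that("total pre-training loss recombines from its components", {
  set.seed(6)
  z1 <- matrix(rnorm(12), 4, 3); z2 <- matrix(rnorm(12), 4, 3)
  cfg <- pretrain_config(lambda_align = 0.7, lambda_style = 0.03)
  parts <- pretrain_total_loss(z1, z2, cfg)
  expect_lt(abs(parts$total - (0.7 * parts$align + 0.03 * parts$style)),
            1e-12)
  cfg0 <- pretrain_config(lambda_style = 0)
  expect_equal(pretrain_total_loss(z1, z1, cfg0)$total, 0)
  expect_equal(pretrain_total_loss(z1, -z1, cfg0)$total, 4)
})

test_that("pre-training runs, is seeded, and no-ops at zero loss weights", {
  set.seed(7)
  x <- array(rnorm(512 * 8 * 5), c(512, 8, 5))
  cfg <- pretrain_config(epochs = 2L, batch_size = 256L, d_model = 16L,
                         seed = 3L)
  pre <- run_pretraining(x, cfg)
  expect_identical(nrow(pre$history), 2L)
  expect_true(all(is.finite(pre$history$total)))

  # smoke training property: the objective trends down once the epoch
  # horizon is long enough for the trend to dominate the fresh-view
  # sampling noise of individual epochs
  drops <- vapply(1:5, function(s) {
    h <- run_pretraining(x, pretrain_config(epochs = 10L,
                                            batch_size = 256L,
                                            d_model = 16L,
                                            seed = s))$history$total
    mean(h[9:10]) <= mean(h[1:2])
  }, logical(1))
  expect_gte(sum(drops), 4L)

  pre2 <- run_pretraining(x, cfg)
  expect_identical(pre$params, pre2$params)     # bitwise seed determinism
  expect_identical(pre$history, pre2$history)

  cfg0 <- pretrain_config(lambda_align = 0, lambda_style = 0, epochs = 2L,
                          batch_size = 256L, d_model = 16L, seed = 3L)
  set.seed(3); init <- extractor_init(40, 16)
  pre0 <- run_pretraining(x, cfg0, params = init)
  expect_identical(pre0$params, init)           # zero gradient -> unchanged

  expect_error(run_pretraining(x[0, , , drop = FALSE], cfg), "empty")
})

test_that("the style loss alone drives off-diagonal Gram entries down", {
  set.seed(8)
  x <- array(rnorm(4 * 8 * 5), c(4, 8, 5))
  cfg <- pretrain_config(lambda_align = 0, lambda_style = 1, epochs = 200L,
                         batch_size = 4L, d_model = 8L, seed = 1L)
  pre <- run_pretraining(x, cfg, views = c("identity", "identity"))
  h <- pre$history$style
  expect_lt(h[200], h[1])
  expect_lt(h[200], h[100])
  expect_lt(h[100], h[1])
  # final embeddings are near-orthonormal rows
  z <- extract_features(de_flatten(x), pre$params)
  u <- z / sqrt(rowSums(z^2))
  g <- tcrossprod(u)
  expect_lt(max(abs(g - diag(4))), 0.2)
})
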