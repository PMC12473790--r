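test_that("noise scale follows the capped affine rule", {
  expect_equal(compute_noise_scale(array(0, c(2, 3, 5))), 1e-8)
  # cap saturates: 0.1 * 1.0 > 0.05
  expect_equal(compute_noise_scale(matrix(1, 4, 5)), 0.05)
  # below the cap: 0.1 * 0.2 + 1e-8
  expect_equal(compute_noise_scale(matrix(0.2, 4, 5)), 0.02 + 1e-8)
  # always in (0, cap]
  set.seed(7)
  for (i in 1:200) {
    s <- compute_noise_scale(array(rnorm(30, sd = runif(1, 0, 3)), c(2, 3, 5)))
    expect_gt(s, 0); expect_lte(s, 0.05)
  }
})

test_that("the noise view adds Gaussian noise at the computed scale", {
  x0 <- array(0, c(3, 4, 5))
  set.seed(1)
  out <- nerm_view(x0)
  expect_lt(max(abs(out)), 6e-8)   # scale is the 1e-8 floor

  set.seed(5); a <- nerm_view(array(1, c(2, 62, 5)))
  set.seed(5); b <- nerm_view(array(1, c(2, 62, 5)))
  expect_identical(a, b)

  # Monte-Carlo: sd of injected noise matches s_noise within 1%
  x <- array(1, c(200, 100, 5))   # 1e5 entries, mean|X| = 1 -> s = 0.05
  set.seed(11)
  resid <- nerm_view(x) - x
  expect_lt(abs(sd(resid) / 0.05 - 1), 0.01)
})

test_that("Haar analysis/synthesis matches the orthogonal-matrix oracle", {
  r2 <- sqrt(2)
  co <- haar_dwt1(rep(1, 5))
  expect_equal(co$cA, rep(r2, 3)); expect_equal(co$cD, rep(0, 3))
  expect_equal(haar_dwt1(rep(0, 5)), list(cA = rep(0, 3), cD = rep(0, 3)))
  expect_equal(haar_idwt1(rep(r2, 3), rep(0, 3)), rep(1, 5))
  expect_equal(haar_idwt1(rep(0, 3), rep(0, 3)), rep(0, 5))
  expect_error(haar_dwt1(rep(1, 4)), "length 5")
  expect_error(haar_idwt1(1, rep(0, 3)), "length 3")

  # oracle: explicit orthogonal 6x6 Haar matrix acting on the padded signal
  W <- matrix(0, 6, 6)
  for (k in 1:3) {
    W[k, 2 * k - 1] <- 1 / r2;     W[k, 2 * k] <- 1 / r2
    W[3 + k, 2 * k - 1] <- 1 / r2; W[3 + k, 2 * k] <- -1 / r2
  }
  expect_equal(W %*% t(W), diag(6))   # orthogonality of the oracle itself
  P <- rbind(diag(5), c(0, 0, 0, 0, 1))  # pad-by-repeat matrix
  set.seed(3)
  for (i in 1:200) {
    x <- rnorm(5)
    cf <- W %*% (P %*% x)
    got <- haar_dwt1(x)
    expect_lt(max(abs(got$cA - cf[1:3])), 1e-12)
    expect_lt(max(abs(got$cD - cf[4:6])), 1e-12)
    expect_lt(max(abs(haar_idwt1(got$cA, got$cD) - x)), 1e-12)
  }
  # vectorised path agrees with the per-vector path
  xb <- array(rnorm(4 * 3 * 5), c(4, 3, 5))
  cb <- cate:::haar_dwt_array(xb)
  for (b in 1:4) for (ch in 1:3) {
    one <- haar_dwt1(xb[b, ch, ])
    expect_equal(cb$cA[b, ch, ], one$cA)
    expect_equal(cb$cD[b, ch, ], one$cD)
  }
  expect_equal(cate:::haar_idwt_array(cb$cA, cb$cD), xb)
})

test_that("mask probabilities and precedence behave as configured", {
  set.seed(1)
  m0 <- sample_masks(c(10, 10, 3), mask_config(mu = 0))
  expect_true(all(m0$m_a == 0) && all(m0$m_suppress == 0) &&
                all(m0$m_enhance == 0))

  set.seed(2)
  n <- c(100, 100, 100)   # 1e6 draws
  mk <- sample_masks(n, mask_config(mu = 0.05))
  tol3 <- function(p) 3 * sqrt(p * (1 - p) / prod(n))
  expect_lt(abs(mean(mk$m_a) - 0.025), tol3(0.025))
  expect_lt(abs(mean(mk$m_suppress) - 0.05), tol3(0.05))
  expect_lte(mean(mk$m_enhance), 0.025 + tol3(0.025))
  # suppression wins: no overlap survives
  expect_identical(sum(mk$m_suppress * mk$m_enhance), 0)

  set.seed(9); a <- sample_masks(c(4, 4, 3), mask_config())
  set.seed(9); b <- sample_masks(c(4, 4, 3), mask_config())
  expect_identical(a, b)
})

test_that("coefficient perturbation applies the piecewise multipliers", {
  dims <- c(1, 1, 3)
  cA <- array(c(1, 2, 3), dims); cD <- array(c(2, -1, 0.5), dims)
  zero <- array(0, dims); one <- array(1, dims)
  draws <- list(eps_a = one, eps_d = one, sigma_d = array(0.3, dims))
  masks0 <- list(m_a = zero, m_suppress = zero, m_enhance = zero)
  expect_equal(perturb_coeffs(cA, cD, masks0, draws), list(cA = cA, cD = cD))

  # a single suppressed cell is halved: cD = 2 -> 1
  ms <- list(m_a = zero, m_suppress = array(c(1, 0, 0), dims),
             m_enhance = zero)
  expect_equal(perturb_coeffs(cA, cD, ms, draws)$cD[1, 1, 1], 1)

  # an enhanced cell with eps = 1, sigma = 0.3 -> multiplier 1.3
  me <- list(m_a = zero, m_suppress = zero,
             m_enhance = array(c(1, 0, 0), dims))
  expect_equal(perturb_coeffs(cA, cD, me, draws)$cD[1, 1, 1], 2 * 1.3)

  # approximation branch: masked cell scaled by 1 + amp * eps
  ma <- list(m_a = array(c(1, 0, 0), dims), m_suppress = zero,
             m_enhance = zero)
  got <- perturb_coeffs(cA, cD, ma, draws, mask_config(mu = 0.05))
  expect_equal(got$cA[1, 1, 1], 1 * (1 + 0.05 * 1))

  # literal form zeroes cells hit by neither detail mask
  lit <- perturb_coeffs(cA, cD, ms, draws,
                        mask_config(mu = 0.05, eq6_literal = TRUE))
  expect_equal(lit$cD[1, 1, 1], 1)       # suppressed: halved
  expect_equal(lit$cD[1, 1, 2], 0)       # unmasked: zeroed
})

test_that("wavelet view: identity at mu = 0, determinism, pair structure", {
  set.seed(4)
  x <- array(rnorm(50 * 62 * 5), c(50, 62, 5))
  out <- wtrm_view(x, mcfg = mask_config(mu = 0))
  expect_lt(max(abs(out - x)), 1e-10)

  set.seed(8); a <- wtrm_view(x)
  set.seed(8); b <- wtrm_view(x)
  expect_identical(a, b)
  expect_true(all(is.finite(a)))
  expect_identical(dim(a), dim(x))

  # constant band profile: detail coefficients are zero, so Haar synthesis
  # keeps the bands within each coefficient pair equal even when the
  # approximation coefficients are perturbed
  xc <- array(rep(2, 3 * 4 * 5), c(3, 4, 5))
  set.seed(10)
  oc <- wtrm_view(xc, mcfg = mask_config(mu = 0.9))
  expect_equal(oc[, , 1], oc[, , 2])
  expect_equal(oc[, , 3], oc[, , 4])
})
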