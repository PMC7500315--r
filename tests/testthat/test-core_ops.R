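test_that("bilinear pooling matches the worked outer-product example", {
  A <- array(0, c(2, 2, 1)); A[, 1, 1] <- c(1, 3); A[, 2, 1] <- c(2, 4)
  B <- array(0, c(2, 2, 1)); B[, 1, 1] <- c(5, 7); B[, 2, 1] <- c(6, 8)
  v <- bilinear_pool(A, B)
  expect_equal(matrix(v, 2, 2, byrow = TRUE),
               matrix(c(17, 23, 39, 53), 2, byrow = TRUE))
  expect_identical(attr(v, "stream_dims"), c(2L, 2L))
})

test_that("bilinear pooling handles degenerate and error cases", {
  z <- bilinear_pool(array(0, c(3, 2, 2)), array(0, c(4, 2, 2)))
  expect_equal(as.numeric(z), rep(0, 12))
  # 1x1 spatial, single channel, value v in both maps -> v^2
  v <- 1.7
  expect_equal(as.numeric(bilinear_pool(array(v, c(1, 1, 1)),
                                        array(v, c(1, 1, 1)))), v^2)
  expect_error(bilinear_pool(array(0, c(2, 2, 2)), array(0, c(2, 3, 2))),
               "spatial")
  expect_error(bilinear_pool(array(NaN, c(1, 1, 1)), array(0, c(1, 1, 1))),
               "finite")
})

test_that("bilinear pooling agrees with the triple-loop oracle", {
  set.seed(41)
  for (i in 1:120) {
    Ca <- sample(1:8, 1); Cb <- sample(1:8, 1)
    H <- sample(1:5, 1); W <- sample(1:5, 1)
    fa <- rand_fmap(Ca, H, W); fb <- rand_fmap(Cb, H, W)
    v <- as.numeric(bilinear_pool(fa, fb))
    ref <- oracle_bilinear(fa, fb)
    expect_lt(max(abs(v - ref)) / max(1e-12, max(abs(ref))), 1e-6)
  }
  # mean pooling divides by the number of locations
  fa <- rand_fmap(3, 4, 2); fb <- rand_fmap(2, 4, 2)
  expect_equal(as.numeric(bilinear_pool(fa, fb, pooling = "mean")),
               oracle_bilinear(fa, fb, pooling = "mean"))
})

test_that("bilinear pooling is linear in each stream", {
  set.seed(5)
  A <- rand_fmap(3, 3, 3); B <- rand_fmap(4, 3, 3)
  expect_equal(as.numeric(bilinear_pool(2.5 * A, B)),
               2.5 * as.numeric(bilinear_pool(A, B)))
  expect_equal(as.numeric(bilinear_pool(A, -0.5 * B)),
               -0.5 * as.numeric(bilinear_pool(A, B)))
})

test_that("fast pooling equals self-pooling and is symmetric PSD", {
  f <- array(0, c(2, 1, 1)); f[, 1, 1] <- c(2, 3)
  expect_equal(matrix(bilinear_pool_fast(f), 2, 2, byrow = TRUE),
               matrix(c(4, 6, 6, 9), 2, byrow = TRUE))
  set.seed(7)
  for (i in 1:10) {
    f <- rand_fmap(sample(2:6, 1), sample(1:4, 1), sample(1:4, 1))
    expect_equal(as.numeric(bilinear_pool_fast(f)),
                 as.numeric(bilinear_pool(f, f)))
    M <- matrix(bilinear_pool_fast(f), dim(f)[1], dim(f)[1], byrow = TRUE)
    expect_equal(M, t(M))
    expect_gte(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8 * max(abs(M)))
  }
})

test_that("pooled descriptors are orderless under spatial permutation", {
  set.seed(11)
  f <- rand_fmap(4, 3, 3)
  base <- as.numeric(bilinear_pool_fast(f))
  L <- 9
  for (i in 1:10) {
    perm <- sample(L)
    fm <- matrix(f, 4, L)[, perm]
    fp <- array(fm, c(4, 3, 3))
    expect_lt(max(abs(as.numeric(bilinear_pool_fast(fp)) - base)),
              1e-6 * max(abs(base)))
  }
})

test_that("signed square root preserves sign pattern and composes", {
  expect_identical(signed_sqrt(c(4, -9, 0)), c(2, -3, 0))
  expect_identical(signed_sqrt(1), 1)
  expect_equal(signed_sqrt(signed_sqrt(16)), 2)
  expect_error(signed_sqrt(c(1, Inf)), "finite")
})

test_that("l2 normalization yields unit vectors with a safe zero case", {
  expect_equal(l2_normalize(c(3, 4)), c(0.6, 0.8))
  u <- c(1, 0, 0)
  expect_equal(l2_normalize(u), u)
  z <- l2_normalize(numeric(5))
  expect_identical(z, numeric(5))
  expect_false(anyNA(z))
})

test_that("signed-sqrt + l2 chain produces unit-norm descriptors", {
  set.seed(13)
  for (i in 1:50) {
    v <- stats::rnorm(sample(2:300, 1), sd = 10^stats::runif(1, -2, 3))
    n <- sqrt(sum(l2_normalize(signed_sqrt(v))^2))
    expect_lt(abs(n - 1), 1e-6)
  }
})

test_that("squeeze is the per-channel spatial mean", {
  expect_equal(se_squeeze(array(5, c(3, 2, 4))), rep(5, 3))
  f <- array(c(1, 2, 3, 4), c(1, 2, 2))
  expect_equal(se_squeeze(f), 2.5)
  expect_equal(se_squeeze(array(0, c(2, 3, 3))), c(0, 0))
})

test_that("excitation gate lies in (0,1) and matches a scalar oracle", {
  p0 <- se_params(4, 2, init = "zero")
  expect_equal(se_excite(c(1, -2, 3, 0.5), p0), rep(0.5, 4))
  ph <- se_params(4, 2, init = "he", seed = 3)
  expect_equal(se_excite(numeric(4), ph), rep(0.5, 4))
  set.seed(21)
  for (i in 1:25) {
    C <- sample(c(2, 4, 6, 8), 1)
    r <- sample(c(1, 2), 1)
    W1 <- matrix(stats::rnorm(C / r * C), C / r, C)
    W2 <- matrix(stats::rnorm(C * C / r), C, C / r)
    s <- stats::rnorm(C)
    e <- se_excite(s, list(W1 = W1, W2 = W2, reduction_ratio = r))
    expect_equal(e, oracle_se_excite(s, W1, W2), tolerance = 1e-10)
    expect_true(all(e > 0 & e < 1))
  }
  expect_error(se_excite(1:3, p0), "match")
  expect_error(se_params(6, 4), "divide")
})

test_that("channel recalibration scales channels and preserves shape", {
  f <- rand_fmap(2, 3, 4)
  expect_equal(se_apply(f, c(1, 1)), f)
  expect_equal(se_apply(f, c(0, 0)), array(0, dim(f)))
  g <- se_apply(f, c(2, 0.5))
  expect_equal(g[1, , ], 2 * f[1, , ])
  expect_equal(g[2, , ], 0.5 * f[2, , ])
  expect_error(se_apply(f, c(1, 1, 1)), "channels")
})
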