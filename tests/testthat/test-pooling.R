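# MIL pooling operators against independent oracles, plus their invariants.

test_that("max pooling is the columnwise maximum", {
  expect_equal(max_pool_bag(matrix(c(1, 3, 5, 2), nrow = 2)), c(3, 5))
  one <- matrix(rnorm(6), nrow = 1)
  expect_equal(max_pool_bag(one), as.numeric(one))
  set.seed(41)
  E <- random_bag(32, 512)
  z <- max_pool_bag(E)
  loopz <- numeric(512)
  for (d in 1:512) {
    m <- E[1, d]
    for (k in 2:32) if (E[k, d] > m) m <- E[k, d]
    loopz[d] <- m
  }
  expect_identical(z, loopz)
  expect_error(max_pool_bag(matrix(numeric(0), nrow = 0, ncol = 3)), "K")
})

test_that("conv pooling is the kernel-weighted sum across instances", {
  set.seed(42)
  E <- random_bag(8, 5)
  # one-hot kernel selects a row
  u <- rep(0, 8); u[3] <- 1
  expect_equal(conv_pool_bag(E, conv_pool_params(8, u)), as.numeric(E[3, ]))
  # uniform kernel averages
  expect_equal(conv_pool_bag(E, conv_pool_params(8)), colMeans(E))
  # random kernel vs explicit double loop
  u2 <- rnorm(8)
  z <- conv_pool_bag(E, conv_pool_params(8, u2))
  loopz <- numeric(5)
  for (d in 1:5) for (k in 1:8) loopz[d] <- loopz[d] + u2[k] * E[k, d]
  expect_equal(z, loopz, tolerance = 1e-6)
  expect_error(conv_pool_bag(E, conv_pool_params(7)), "does not match")
})

test_that("conv pooling is not permutation-invariant (counterexample)", {
  E <- rbind(c(1, 0), c(0, 1))
  u <- c(1, 0)
  z1 <- conv_pool_bag(E, conv_pool_params(2, u))
  z2 <- conv_pool_bag(E[2:1, ], conv_pool_params(2, u))
  expect_false(isTRUE(all.equal(z1, z2)))
})

test_that("attention pooling matches the formula oracle on small cases", {
  # K=3, D=2, L=2 with small integer parameters
  E <- rbind(c(1, -1), c(2, 0), c(0, 1))
  V <- rbind(c(1, 0), c(-1, 2))
  w <- c(1, -2)
  p <- attention_params(D = 2, L = 2, V = V, w = w)
  got <- attention_pool_bag(E, p)
  ref <- oracle_attention(E, V, w)
  expect_equal(got$a, ref$a, tolerance = 1e-8)
  expect_equal(got$z, ref$z, tolerance = 1e-8)
})

test_that("attention degenerate cases are exact", {
  p <- attention_params(D = 3, L = 4, sd = 0.5)
  # identical rows -> uniform weights, z = the common row
  E <- matrix(rep(c(1, 2, 3), each = 5), nrow = 5)
  r <- attention_pool_bag(E, p)
  expect_equal(r$a, rep(1 / 5, 5), tolerance = 1e-12)
  expect_equal(r$z, c(1, 2, 3), tolerance = 1e-12)
  # K = 1 -> a = 1, z = h_1
  E1 <- matrix(c(-1, 0, 4), nrow = 1)
  r1 <- attention_pool_bag(E1, p)
  expect_identical(r1$a, 1)
  expect_equal(r1$z, c(-1, 0, 4))
})

test_that("attention weights are a stable convex combination", {
  set.seed(43)
  for (i in 1:25) {
    K <- sample(1:40, 1); D <- sample(2:16, 1); L <- sample(2:32, 1)
    scale <- sample(c(1, 100, 1e4), 1)   # drive scores to extreme magnitudes
    E <- random_bag(K, D, scale = scale)
    p <- attention_params(D, L, sd = 1)
    r <- attention_pool_bag(E, p)
    expect_true(all(is.finite(r$a)) && all(is.finite(r$z)))
    expect_lt(abs(sum(r$a) - 1), 1e-6)
    expect_true(all(r$a > 0))
    # convex hull per channel (tolerance scales with the magnitudes)
    tol <- 1e-9 * max(1, scale)
    expect_true(all(r$z >= apply(E, 2, min) - tol))
    expect_true(all(r$z <= apply(E, 2, max) + tol))
  }
})

test_that("attention and max pooling are permutation-invariant", {
  set.seed(44)
  E <- random_bag(12, 6)
  p <- attention_params(6, 8, sd = 0.5)
  base <- attention_pool_bag(E, p)
  zmax <- max_pool_bag(E)
  for (i in 1:20) {
    perm <- sample(12)
    rp <- attention_pool_bag(E[perm, ], p)
    expect_equal(rp$z, base$z, tolerance = 1e-12)
    expect_equal(rp$a, base$a[perm], tolerance = 1e-12)
    expect_equal(max_pool_bag(E[perm, ]), zmax)
  }
})

test_that("softmax weights are invariant to a constant score shift", {
  set.seed(45)
  s <- rnorm(16, sd = 3)
  for (c in c(-1e4, -1, 0.5, 1e4)) {
    expect_equal(dmilct:::softmax_stable(s + c), dmilct:::softmax_stable(s),
                 tolerance = 1e-12)
  }
})

test_that("classify_bag is the logistic of the affine score", {
  expect_identical(classify_bag(c(1, 2), list(weight = c(0, 0), bias = 0)),
                   0.5)
  z <- c(2, 3)
  expect_gt(classify_bag(z, list(weight = c(4, 4), bias = 0)), 0.999999)
  set.seed(46)
  for (i in 1:20) {
    D <- sample(1:10, 1)
    z <- rnorm(D); wt <- rnorm(D); b <- rnorm(1)
    expect_equal(classify_bag(z, list(weight = wt, bias = b)),
                 1 / (1 + exp(-(sum(wt * z) + b))), tolerance = 1e-10)
  }
  expect_error(classify_bag(c(1, 2), list(weight = 1, bias = 0)),
               "does not match")
})
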