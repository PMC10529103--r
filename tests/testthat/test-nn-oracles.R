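# Elementwise operations checked against independent brute-force loop
# implementations on random instances.

brute_mean <- function(tensors) {
  out <- array(0, dim(tensors[[1]]))
  for (i in seq_along(out)) {
    s <- 0
    for (t in tensors) s <- s + t[i]
    out[i] <- s / length(tensors)
  }
  out
}

test_that("average_local_features equals the brute-force elementwise mean", {
  t0 <- rand_tensor(c(3, 2, 2), seed = 1)
  expect_equal(average_local_features(list(t0, t0, t0)), t0)
  expect_equal(average_local_features(list(array(0, c(2, 2, 2)), array(2, c(2, 2, 2)))),
               array(1, c(2, 2, 2)))
  for (k in 1:20) {
    tensors <- lapply(1:4, function(i) rand_tensor(c(3, 3, 2), seed = 100 * k + i))
    expect_equal(average_local_features(tensors), brute_mean(tensors), tolerance = 1e-6)
  }
})

test_that("average_local_features is permutation invariant and validates input", {
  tensors <- lapply(1:5, function(i) rand_tensor(c(2, 3, 4), seed = i))
  set.seed(42)
  for (r in 1:5)
    expect_equal(average_local_features(sample(tensors)), average_local_features(tensors))
  expect_error(average_local_features(list()), "non-empty")
  expect_error(average_local_features(list(rand_tensor(c(2, 2, 2)), rand_tensor(c(2, 2, 3)))),
               "share a shape")
})

test_that("z_pool concatenates max and mean over the pooled dimension", {
  cv <- array(3.5, c(4, 4, 6))
  zp <- z_pool(cv)
  expect_equal(dim(zp), c(4, 4, 2))
  expect_true(all(zp == 3.5))

  # channels-first (N, h, w) convention: output 2 x h x w
  x <- rand_tensor(c(5, 3, 3), seed = 2)
  attr(x, "channels_first") <- TRUE
  zf <- z_pool(x)
  expect_equal(dim(zf), c(2, 3, 3))

  for (k in 1:20) {
    x <- rand_tensor(c(5, 3, 3), seed = 300 + k)
    attr(x, "channels_first") <- TRUE
    zf <- z_pool(x)
    for (i in 1:3) for (j in 1:3) {
      slice <- sapply(1:5, function(n) x[n, i, j])
      expect_equal(zf[1, i, j], max(slice), tolerance = 1e-6)
      expect_equal(zf[2, i, j], mean(slice), tolerance = 1e-6)
    }
  }
})

test_that("triplet attention is the brute-force mean of its three branches", {
  for (k in 1:20) {
    x <- rand_tensor(c(8, 8, 4), seed = 400 + k)
    w <- lapply(1:3, function(j) fbanet:::trip_branch_init(k * 10 + j))
    b1 <- triplet_branch(x, "none", w[[1]])
    b2 <- triplet_branch(x, "swap_w_N", w[[2]])
    b3 <- triplet_branch(x, "swap_h_N", w[[3]])
    expected <- array(0, dim(x))
    for (i in seq_along(expected)) expected[i] <- (b1[i] + b2[i] + b3[i]) / 3
    expect_equal(triplet_attention(x, w), expected, tolerance = 1e-6)
    expect_equal(dim(triplet_attention(x, w)), dim(x))
  }
  # identical branch outputs average to themselves
  x <- rand_tensor(c(4, 4, 3), seed = 1)
  b <- triplet_branch(x, "none", fbanet:::trip_branch_init(1))
  expect_equal((b + b + b) / 3, b)
})

test_that("cross_entropy matches the brute-force per-sample double sum", {
  expect_equal(cross_entropy(matrix(c(1, 0), 1, 2), 0), 0)
  expect_equal(cross_entropy(matrix(0.5, 1, 2), 0), log(2))
  expect_equal(cross_entropy(matrix(0.25, 3, 4), c(0, 1, 3)), log(4))
  for (rep in 1:20) {
    set.seed(500 + rep)
    B <- sample(2:6, 1); k <- sample(2:5, 1)
    p <- matrix(stats::rexp(B * k), B, k)
    p <- p / rowSums(p)
    labels <- sample(0:(k - 1), B, replace = TRUE)
    # Brute force: -(1/N) sum_n sum_i y_it log y_ip with one-hot labels
    total <- 0
    for (n in 1:B) for (i in 1:k) {
      y_it <- as.numeric(labels[n] == i - 1)
      total <- total - y_it * log(p[n, i])
    }
    expect_equal(cross_entropy(p, labels), total / B, tolerance = 1e-6)
  }
})

test_that("cross_entropy is finite under degenerate probabilities and validates input", {
  p <- matrix(c(0, 1), 1, 2)
  v <- cross_entropy(p, 0)              # true class has probability zero
  expect_true(is.finite(v) && v > 20)
  expect_error(cross_entropy(matrix(0.6, 1, 2), 0), "sum to 1")
  expect_error(cross_entropy(matrix(0.5, 1, 2), 2), "out of range")
  expect_error(cross_entropy(matrix(0.5, 2, 2), 0), "disagree")
})

test_that("convolution matches a direct nested-loop computation", {
  brute_conv <- function(x, W, k, cout, stride, pad) {
    d <- dim(x)
    hp <- d[1] + 2 * pad; wp <- d[2] + 2 * pad
    xp <- array(0, c(hp, wp, d[3]))
    xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
    ho <- (hp - k) %/% stride + 1; wo <- (wp - k) %/% stride + 1
    y <- array(0, c(ho, wo, cout))
    Wa <- array(W, c(k, k, d[3], cout))
    for (i in 1:ho) for (j in 1:wo) for (co in 1:cout) {
      acc <- 0
      for (a in 1:k) for (b in 1:k) for (ci in 1:d[3])
        acc <- acc + xp[(i - 1) * stride + a, (j - 1) * stride + b, ci] * Wa[a, b, ci, co]
      y[i, j, co] <- acc
    }
    y
  }
  for (rep in 1:5) {
    set.seed(600 + rep)
    x <- rand_tensor(c(6, 6, 2), seed = 600 + rep)
    W <- matrix(rnorm(3 * 3 * 2 * 4), 18, 4)
    f <- fbanet:::conv2d_fwd(array(x, c(6, 6, 2, 1)), W, NULL, stride = 2, pad = 1)
    expect_equal(f$y[, , , 1], brute_conv(x, W, 3, 4, 2, 1), tolerance = 1e-8)
  }
})
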