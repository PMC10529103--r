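test_that("embed_sequence flattens spatial dims and preserves token count", {
  fw <- rand_tensor(c(2, 2, 3), seed = 1)
  seq3 <- embed_sequence(fw)
  expect_equal(dim(seq3), c(3, 4))
  expect_equal(attr(seq3, "hw"), c(2, 2))

  # LayerNorm fixed point: zero positional encoding and rows that are already
  # zero-mean with unit population variance pass through (up to eps)
  row <- c(-1, 1, -1, 1)
  fw2 <- array(0, c(2, 2, 3))
  for (t in 1:3) fw2[, , t] <- matrix(row, 2, 2)
  out <- embed_sequence(fw2, epos = matrix(0, 3, 4))
  expect_equal(unclass(out)[1, ], row, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("single-token attention is the softmax-of-a-scalar case", {
  x <- matrix(rnorm(8), 1, 8)
  w <- fbanet:::mhsa_init(8, seed = 3)
  res <- multi_head_self_attention(x, heads = 2, weights = w, return_attention = TRUE)
  for (A in res$attention) expect_equal(A, matrix(1, 1, 1))
  expect_equal(res$tokens, x + (x %*% w$Wv) %*% w$Wo)
})

test_that("attention rows are probability vectors and W_O = 0 gives the identity", {
  set.seed(5)
  x <- matrix(rnorm(6 * 8), 6, 8)
  res <- multi_head_self_attention(x, heads = 4, return_attention = TRUE, seed = 2)
  for (A in res$attention) {
    expect_true(all(A >= 0 & A <= 1))
    expect_equal(rowSums(A), rep(1, 6), tolerance = 1e-6)
  }
  w0 <- fbanet:::mhsa_init(8, seed = 2)
  w0$Wo <- matrix(0, 8, 8)
  expect_identical(multi_head_self_attention(x, heads = 4, weights = w0), x)
  expect_error(multi_head_self_attention(x, heads = 3), "divisible")
})

test_that("zero-weight residual blocks make the token stack the identity", {
  set.seed(6)
  x <- matrix(rnorm(4 * 64), 4, 64)          # random tokens from a 4 x 8 x 8 block
  wa <- fbanet:::mhsa_init(64, seed = 1)
  wa$Wv <- matrix(0, 64, 64); wa$Wo <- matrix(0, 64, 64)
  wm <- fbanet:::mlp_init(64, seed = 1)
  wm$fc2.W <- matrix(0, 256, 64); wm$fc2.b <- numeric(64)
  out <- x
  for (l in 1:12) {
    out <- multi_head_self_attention(out, heads = 8, weights = wa)
    out <- transformer_mlp(out, weights = wm)
  }
  expect_identical(out, x)                   # bit-exact residual identity
})

test_that("transformer_mlp preserves shape, is deterministic, and stacks", {
  set.seed(7)
  x <- matrix(rnorm(5 * 16), 5, 16)
  w <- fbanet:::mlp_init(16, seed = 4)
  y1 <- transformer_mlp(x, weights = w)
  y2 <- transformer_mlp(x, weights = w)
  expect_identical(y1, y2)
  out <- x
  for (l in 1:12) out <- transformer_mlp(out, weights = w)
  expect_equal(dim(out), dim(x))
  expect_true(all(is.finite(out)))
})

test_that("triplet branch gate saturates to the identity and stays in (0, 1)", {
  x <- rand_tensor(c(8, 8, 4), seed = 8)
  w <- fbanet:::trip_branch_init(1)
  w$W <- matrix(0, 98, 1)
  w$bn.b <- 40                               # sigmoid(40) ~ 1
  expect_equal(triplet_branch(x, "none", w), x, tolerance = 1e-9)

  # gates strictly inside (0, 1) for generic weights: output differs from both
  # the input (gate < 1) and zero (gate > 0), elementwise bounded
  wr <- fbanet:::trip_branch_init(2)
  y <- triplet_branch(x, "none", wr)
  expect_true(all(abs(y) <= abs(x) + 1e-12))
  expect_true(all((y == 0) == (x == 0)))
})

test_that("rotated triplet branches equal the permuted first branch", {
  x <- rand_tensor(c(8, 8, 4), seed = 9)
  w <- fbanet:::trip_branch_init(3)
  # swap_w_N: conjugate branch-1 by the (3, 2, 1) permutation
  expect_equal(triplet_branch(x, "swap_w_N", w),
               aperm(triplet_branch(aperm(x, c(3, 2, 1)), "none", w), c(3, 2, 1)),
               tolerance = 1e-12)
  expect_equal(triplet_branch(x, "swap_h_N", w),
               aperm(triplet_branch(aperm(x, c(1, 3, 2)), "none", w), c(1, 3, 2)),
               tolerance = 1e-12)
})

test_that("bi_level_fuse concatenates operands and honors ablation drops", {
  g <- rand_tensor(c(7, 7, 6), seed = 10)    # global features, c = 6
  sa <- rand_tensor(c(7, 7, 4), seed = 11)
  tr <- rand_tensor(c(7, 7, 4), seed = 12)
  w <- list(W = matrix(rnorm(6 * 4), 6, 4), b = numeric(4))
  fused <- bi_level_fuse(sa, tr, g, weights = w)
  expect_equal(dim(fused), c(7, 7, 12))
  expect_equal(fused[, , 1:4], sa)
  expect_equal(fused[, , 5:8], tr)
  expect_equal(dim(bi_level_fuse(NULL, tr, g, weights = w)), c(7, 7, 8))
  expect_equal(dim(bi_level_fuse(sa, NULL, g, weights = w)), c(7, 7, 8))
  expect_error(bi_level_fuse(NULL, NULL, g, weights = w), "at least one")
  expect_error(bi_level_fuse(rand_tensor(c(5, 5, 4)), tr, g, weights = w), "spatial")
})

test_that("classification head reduces channels, pools, and maps to logits", {
  f <- rand_tensor(c(7, 7, 6), seed = 13)
  w <- list(conv.W = matrix(rnorm(6 * 3), 6, 3), conv.b = numeric(3),
            fc.W = matrix(0, 3, 2), fc.b = numeric(2))
  expect_equal(classification_head(f, 2, weights = w), c(0, 0))
  # GAP of a constant map is the constant, checked through an identity head
  wc <- list(conv.W = diag(3), conv.b = numeric(3),
             fc.W = diag(3), fc.b = numeric(3))
  const <- array(rep(c(1, 2, 3), each = 16), c(4, 4, 3))
  expect_equal(classification_head(const, 3, weights = wc), c(1, 2, 3))
  # width follows num_class (binary screening vs many-class pre-training)
  expect_length(classification_head(f, 2), 2)
  expect_length(classification_head(f, 345), 345)
})
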