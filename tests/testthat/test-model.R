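test_that("forward pass yields finite logits for all named scales and patch counts", {
  xg <- rand_batch(16, 2, seed = 1)
  for (L in c(6, 12, 18)) for (P in c(5, 9)) {
    m <- fbanet(tiny_config(layers = L, num_patches = P))
    f <- fbanet_forward(m, xg)
    expect_equal(dim(f$logits), c(2, 2))
    expect_true(all(is.finite(f$logits)))
  }
})

test_that("every runnable ablation combination runs forward and backward", {
  xg <- rand_batch(16, 2, seed = 2)
  combos <- expand.grid(fe = c(TRUE, FALSE), ta = c(TRUE, FALSE), sa = c(TRUE, FALSE))
  for (r in seq_len(nrow(combos))) {
    m <- fbanet(tiny_config(feature_enhance = combos$fe[r],
                            triplet_attention = combos$ta[r],
                            self_attention = combos$sa[r]))
    gr <- fbanet_grad(m, xg, c(0L, 1L))
    expect_true(is.finite(gr$loss))
    expect_true(all(vapply(gr$grads, function(g) all(is.finite(g)), logical(1))))
  }
})

test_that("attention softmax rows sum to one across layers and heads", {
  m <- fbanet(tiny_config(layers = 3, heads = 4))
  xg <- rand_batch(16, 3, seed = 3)
  f <- fbanet_forward(m, xg)
  lay <- f$cache$cs$layers
  expect_length(lay, 3)
  n_checked <- 0
  for (lc in lay) for (A in lc$mhsa$A) {
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
    expect_true(all(A >= 0 & A <= 1))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 3 * 4 * 3)   # layers x heads x batch
})

test_that("parameter counts are deterministic, patch-invariant, with equal layer increments", {
  cfg <- function(L, P = 5) fbanet_config(layers = L, num_patches = P)
  expect_identical(count_trainable_parameters(cfg(12)), count_trainable_parameters(cfg(12)))
  p6 <- count_trainable_parameters(cfg(6))
  p12 <- count_trainable_parameters(cfg(12))
  p18 <- count_trainable_parameters(cfg(18))
  expect_identical(p12 - p6, p18 - p12)
  for (L in c(6, 12, 18))
    expect_identical(count_trainable_parameters(cfg(L, 5)), count_trainable_parameters(cfg(L, 9)))
  # strictly increasing in depth and in adjusted channel count
  expect_true(p6 < p12 && p12 < p18)
  n1 <- count_trainable_parameters(tiny_config(adjusted_channels = 8))
  n2 <- count_trainable_parameters(tiny_config(adjusted_channels = 16))
  expect_true(n1 < n2)
  # a built model materializes exactly the declared shapes
  m <- fbanet(tiny_config())
  expect_identical(sum(vapply(m$params, length, numeric(1))),
                   count_trainable_parameters(m))
})

test_that("gradient flows to every trainable parameter group", {
  m <- fbanet(tiny_config(layers = 2))
  xg <- rand_batch(16, 4, seed = 4)
  gr <- fbanet_grad(m, xg, c(0L, 1L, 1L, 0L))
  expect_gt(gr$loss, 0)
  expect_setequal(names(gr$grads), names(m$params))
  zero_groups <- names(gr$grads)[vapply(gr$grads, function(g) max(abs(g)) == 0, logical(1))]
  expect_length(zero_groups, 0)
})

test_that("analytic gradients match finite differences on the assembled model", {
  m <- fbanet(tiny_config(layers = 2, seed = 5))
  xg <- rand_batch(16, 2, seed = 5)
  labels <- c(0L, 1L)
  gr <- fbanet_grad(m, xg, labels)
  eps <- 1e-5
  set.seed(6)
  for (nm in c("adjust.W", "attn.1.mhsa.Wq", "attn.2.mlp.fc1.W", "trip.2.W",
               "gproj.W", "stem.3.W", "fc.W")) {
    i <- sample(length(m$params[[nm]]), 1)
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
    fd <- (fbanet_grad(mp, xg, labels)$loss - fbanet_grad(mm, xg, labels)$loss) / (2 * eps)
    expect_equal(gr$grads[[nm]][i], fd, tolerance = 1e-3)
  }
})

test_that("the stem is shared and deterministic with the declared downsampling", {
  m <- fbanet(tiny_config())
  imgs <- lapply(1:3, function(i) rand_tensor(c(16, 16, 3), seed = i))
  feats <- stem_forward(imgs, m)
  expect_length(feats, 3)
  shapes <- lapply(feats, dim)
  expect_true(all(vapply(shapes, identical, logical(1), shapes[[1]])))
  expect_equal(shapes[[1]], c(2, 2, 32))     # 16 px / 8x downsampling
  # identical inputs give identical outputs (inference determinism)
  again <- stem_forward(list(imgs[[1]], imgs[[1]]), m)
  expect_identical(again[[1]], again[[2]])
  expect_error(stem_forward(list(imgs[[1]], rand_tensor(c(8, 8, 3))), m), "same side")
})

test_that("the full residual stem builds, runs, and counts like its reference", {
  cfg <- fbanet_config(num_patches = 5, layers = 1, heads = 2, adjusted_channels = 4,
                       num_class = 2, input_side = 32, stem = "resnet50", seed = 1)
  # 50-layer bottleneck backbone without classifier: ~23.5 M weights
  stem_n <- sum(vapply(fbanet_param_shapes(cfg)[grep("^stem\\.", names(fbanet_param_shapes(cfg)))],
                       prod, numeric(1)))
  expect_equal(stem_n, 23508032)
  m <- fbanet(cfg)
  xg <- rand_batch(32, 1, seed = 50)
  gr <- fbanet_grad(m, xg, 0L)
  expect_true(is.finite(gr$loss))
  expect_true(all(vapply(gr$grads, function(g) all(is.finite(g)), logical(1))))
})

test_that("feature_enhance concatenates 2c channels then adjusts, with ablation bypass", {
  la <- rand_tensor(c(2, 2, 4), seed = 7)
  gf <- rand_tensor(c(2, 2, 4), seed = 8)
  # identity-initialized 1x1 kernel on N = 2c returns the raw concatenation
  w_id <- list(W = diag(8), b = numeric(8))
  out <- feature_enhance(la, gf, adjusted_channels = 8, weights = w_id)
  expect_equal(out[, , 1:4], la)
  expect_equal(out[, , 5:8], gf)
  # bypass keeps the output channel count
  w <- list(W = matrix(rnorm(4 * 6), 4, 6), b = numeric(6))
  off <- feature_enhance(la, gf, weights = w, enhance = FALSE)
  expect_equal(dim(off), c(2, 2, 6))
  expect_error(feature_enhance(rand_tensor(c(3, 3, 4)), gf), "shapes differ")
})

test_that("checkpoints round-trip bit-exactly and head transfer retains weights", {
  m <- fbanet(tiny_config(num_class = 10, seed = 9))
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path))
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$buffers, m$buffers)

  mt <- transfer_head(m, 2)
  expect_equal(mt$config$num_class, 2L)
  expect_equal(dim(mt$params$fc.W), c(8, 2))
  same <- setdiff(names(m$params), c("fc.W", "fc.b"))
  expect_identical(mt$params[same], m$params[same])
  expect_identical(mt$params$epos, m$params$epos)
})

test_that("predict returns coherent probabilities and classes", {
  m <- fbanet(tiny_config())
  ds <- small_htp(n = 6, canvas = 96)
  pr <- predict(m, ds)
  expect_equal(dim(pr), c(6, 2))
  expect_equal(rowSums(pr), rep(1, 6), tolerance = 1e-8)
  cl <- predict(m, ds, type = "class")
  expect_true(all(cl %in% c(0L, 1L)))
  lg <- predict(m, ds$images[[1]], type = "logit")
  expect_equal(dim(lg), c(1, 2))
})
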