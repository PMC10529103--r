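test_that("warmup-cosine schedule has the protocol's shape and endpoints", {
  expect_equal(lr_at_step(10, 100, 10, 0.03), 0.03)     # warmup endpoint
  expect_equal(lr_at_step(0, 100, 10, 0.03), 0)
  expect_lt(lr_at_step(9999, 10000, 100, 0.03), 1e-6)   # cos(pi) ~ -1 at the end
  # continuity at the warmup boundary
  lr <- lr_at_step(0:99, 100, 10, 1)
  expect_lt(abs(lr[11] - lr[10]), abs(lr[10] - lr[9]) + 0.2)
  # non-increasing after warmup
  expect_true(all(diff(lr[11:100]) <= 1e-12))
  # base learning rates of the two phases
  expect_equal(train_config("pretrain")$base_lr, 3e-2)
  expect_equal(train_config("finetune")$base_lr, 1e-3)
  expect_equal(train_config("pretrain")$batch_size, 40L)
  expect_equal(train_config("finetune")$batch_size, 16L)
  expect_equal(train_config("finetune")$epochs, 10L)
  expect_error(lr_at_step(100, 100, 10, 0.03), "out of range")
})

test_that("stratified folds partition the data and preserve class balance", {
  labels <- rep(c(0L, 1L), each = 5)
  folds <- stratified_kfold(labels, 5, seed = 1)
  for (f in folds) {
    expect_length(f$val_indices, 2)
    expect_equal(sort(labels[f$val_indices]), c(0L, 1L))
    expect_setequal(c(f$train_indices, f$val_indices), 1:10)
    expect_length(intersect(f$train_indices, f$val_indices), 0)
  }
  # union of validation folds is the full index set with no repeats
  all_val <- unlist(lapply(folds, `[[`, "val_indices"))
  expect_equal(sort(all_val), 1:10)

  # the clinical corpus composition: 1296 vs 319 into five folds
  labels2 <- c(rep(0L, 1296), rep(1L, 319))
  folds2 <- stratified_kfold(labels2, 5, seed = 3)
  sizes <- vapply(folds2, function(f) length(f$val_indices), numeric(1))
  minority <- vapply(folds2, function(f) sum(labels2[f$val_indices]), numeric(1))
  expect_equal(sizes, rep(323, 5))
  expect_true(all(minority %in% c(63, 64)))
  expect_equal(sum(minority), 319)
  # stratification bound on the class-1 fraction deviation
  dev <- abs(minority / sizes - 319 / 1615)
  expect_true(all(dev <= 1 / 323))

  expect_error(stratified_kfold(c(0, 0, 0, 1), 3), "at least k")
  # determinism
  expect_identical(stratified_kfold(labels2, 5, seed = 3), folds2)
})

test_that("augmentation flips only the training split and is seed-deterministic", {
  img <- small_htp(n = 2, canvas = 96)$images[[1]]
  va <- augment(img, "val", rng_seed = 1)
  expect_identical(va$pixels, img$pixels)
  expect_equal(dim(attr(va, "tensor")), dim(img$pixels))

  a1 <- augment(img, "train", rng_seed = 7)
  a2 <- augment(img, "train", rng_seed = 7)
  expect_identical(a1$pixels, a2$pixels)

  # double flip is the identity on geometry
  px <- img$pixels
  expect_identical(fbanet:::flip_array(fbanet:::flip_array(px, TRUE), TRUE), px)
  expect_identical(fbanet:::flip_array(fbanet:::flip_array(px, FALSE, TRUE), FALSE, TRUE), px)
})

test_that("a zero-learning-rate step leaves parameters bit-identical", {
  m <- fbanet(tiny_config())
  xg <- rand_batch(16, 2, seed = 10)
  gr <- fbanet_grad(m, xg, c(0L, 1L))
  upd <- fbanet:::sgd_step(m$params, gr$grads, list(), lr = 0, momentum = 0.9)
  expect_identical(upd$params, m$params)
})

test_that("loss of a freshly initialized model is calibrated to ln(num_class)", {
  for (k in c(2, 5)) {
    m <- fbanet(tiny_config(num_class = k, seed = 11))
    xg <- rand_batch(16, 8, seed = 11)
    set.seed(12)
    labels <- sample(0:(k - 1), 8, replace = TRUE)
    loss <- fbanet_grad(m, xg, labels, train = FALSE)$loss
    expect_equal(loss, log(k), tolerance = 0.02)
  }
})

test_that("fine-tuning is reproducible and reports one fold per split", {
  ds <- small_htp(n = 18, seed = 3, canvas = 96, class1_fraction = 1 / 3)
  cfg <- tiny_config()
  tc <- train_config("finetune", epochs = 2, folds = 3, batch_size = 6, seed = 5)
  cv1 <- run_finetune(cfg, tc, ds)
  cv2 <- run_finetune(cfg, tc, ds)
  expect_s3_class(cv1, "fbanet_cv")
  expect_length(cv1$folds, 3)
  for (f in seq_len(3)) {
    expect_identical(cv1$folds[[f]]$history, cv2$folds[[f]]$history)
    expect_s3_class(cv1$folds[[f]]$metrics, "fbanet_metrics")
  }
  expect_identical(cv1$average, cv2$average)
  # aggregation is mean / max of the fold metrics
  accs <- vapply(cv1$folds, function(f) f$metrics$accuracy, numeric(1))
  expect_equal(cv1$average$accuracy, mean(accs))
  expect_equal(cv1$max$accuracy, max(accs))
})

test_that("pre-training reduces the loss and transfers to a two-class head", {
  qd <- generate_quickdraw_like(qd_gen_params(n_classes = 4, n_train = 6, n_val = 2,
                                              n_test = 1, canvas_side = 96, seed = 2))
  cfg <- tiny_config(num_class = 4)
  tc <- train_config("pretrain", epochs = 4, batch_size = 8, seed = 2)
  pre <- run_pretrain(cfg, tc, qd)
  h <- pre$history
  expect_equal(nrow(h), 4)
  expect_lt(h$train_loss[4], h$train_loss[1])
  # checkpoint round trip reproduces the validation loss exactly
  path <- tempfile(fileext = ".rds"); on.exit(unlink(path))
  save_checkpoint(pre$model, path)
  m2 <- load_checkpoint(path)
  ds_eval <- sketch_dataset(qd$images[qd$split == "val"], qd$labels[qd$split == "val"],
                            num_class = 4)
  e1 <- evaluate_model(pre$model, ds_eval)
  e2 <- evaluate_model(m2, ds_eval)
  expect_identical(e1$loss, e2$loss)
  # head width changes many-class -> binary with all other weights retained
  ft <- transfer_head(m2, 2)
  expect_equal(ncol(ft$params$fc.W), 2)
  keep <- setdiff(names(m2$params), c("fc.W", "fc.b"))
  expect_identical(ft$params[keep], m2$params[keep])
})

test_that("cross-entropy from logits agrees with the probability form", {
  set.seed(13)
  logits <- matrix(rnorm(6 * 3), 6, 3)
  labels <- sample(0:2, 6, replace = TRUE)
  ce <- fbanet:::cross_entropy_logits(logits, labels)
  p <- exp(logits) / rowSums(exp(logits))
  expect_equal(ce$loss, cross_entropy(p, labels), tolerance = 1e-10)
  # gradient of the mean loss is (softmax - onehot) / B
  oh <- matrix(0, 6, 3); oh[cbind(1:6, labels + 1)] <- 1
  expect_equal(ce$dlogits, (p - oh) / 6, tolerance = 1e-10)
})
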