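#' Training configuration
#'
#' Defaults follow the transfer-learning protocol: supervised pre-training
#' for 50 epochs with SGD at base learning rate 3e-2 and batch size 40;
#' fine-tuning under five-fold stratified cross-validation, 10 epochs per
#' fold, base learning rate 1e-3, batch size 16, no frozen parameters. Both
#' phases use a warmup-cosine schedule with one epoch of linear warmup.
#'
#' @param phase `"pretrain"` or `"finetune"`.
#' @param epochs,base_lr,batch_size optimizer settings (phase defaults above).
#' @param warmup_epochs linear warmup length in epochs (default 1).
#' @param momentum SGD momentum (default 0.9).
#' @param weight_decay L2 penalty coefficient (default 0).
#' @param folds stratified fold count k for fine-tuning (default 5).
#' @param hflip,vflip random horizontal/vertical flip augmentation on the
#'   training split (validation data are only normalized).
#' @param seed master seed for fold assignment, shuffling and augmentation.
#' @return An object of class `fbanet_train_config`.
#' @export
train_config <- function(phase = c("finetune", "pretrain"), epochs = NULL,
                         base_lr = NULL, batch_size = NULL, warmup_epochs = 1,
                         momentum = 0.9, weight_decay = 0, folds = 5,
                         hflip = TRUE, vflip = TRUE, seed = 0) {
  phase <- match.arg(phase)
  def <- if (phase == "pretrain") list(epochs = 50, base_lr = 3e-2, batch_size = 40)
         else list(epochs = 10, base_lr = 1e-3, batch_size = 16)
  structure(
    list(phase = phase, epochs = as.integer(epochs %||% def$epochs),
         base_lr = base_lr %||% def$base_lr,
         batch_size = as.integer(batch_size %||% def$batch_size),
         warmup_epochs = warmup_epochs, momentum = momentum,
         weight_decay = weight_decay, folds = as.integer(folds),
         hflip = isTRUE(hflip), vflip = isTRUE(vflip), seed = as.integer(seed)),
    class = "fbanet_train_config")
}

#' @export
print.fbanet_train_config <- function(x, ...) {
  cat(sprintf("<train_config %s: %d epochs, lr %g, batch %d, momentum %g%s>\n",
              x$phase, x$epochs, x$base_lr, x$batch_size, x$momentum,
              if (x$phase == "finetune") sprintf(", %d folds", x$folds) else ""))
  invisible(x)
}

#' Cross-entropy loss
#'
#' Mean over the batch of the negative log probability of the true class.
#' Probabilities are clamped away from zero so the loss is always finite.
#'
#' @param probabilities `B x k` row-stochastic matrix.
#' @param labels integer vector of true classes in `0..k-1`.
#' @return Non-negative scalar loss.
#' @examples
#' cross_entropy(matrix(0.5, 1, 2), 0)  # log(2)
#' @export
cross_entropy <- function(probabilities, labels) {
  p <- as.matrix(probabilities)
  if (nrow(p) != length(labels)) stopf("probabilities and labels disagree in length")
  rs <- rowSums(p)
  if (any(abs(rs - 1) > 1e-6)) stopf("probability rows must sum to 1")
  if (any(labels < 0 | labels >= ncol(p))) stopf("labels out of range")
  pt <- p[cbind(seq_len(nrow(p)), labels + 1L)]
  mean(-log(pmax(pt, 1e-12)))
}

# Numerically stable loss + gradient from logits (log-sum-exp).
cross_entropy_logits <- function(logits, labels) {
  B <- nrow(logits)
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  lt <- logits[cbind(seq_len(B), labels + 1L)]
  loss <- mean(lse - lt)
  sm <- exp(logits - lse)
  sm[cbind(seq_len(B), labels + 1L)] <- sm[cbind(seq_len(B), labels + 1L)] - 1
  list(loss = loss, dlogits = sm / B)
}

#' Warmup-cosine learning-rate schedule
#'
#' Linear ramp from 0 to `base_lr` over `warmup_steps`, then half-cosine
#' decay to 0 at `total_steps`. Continuous at the warmup boundary and
#' non-increasing afterwards.
#'
#' @param step 0-based step index, `0 <= step < total_steps`.
#' @param total_steps total optimization steps.
#' @param warmup_steps warmup length in steps (one epoch's worth of batches
#'   under the default protocol).
#' @param base_lr peak learning rate.
#' @return The learning rate at `step`.
#' @examples
#' lr_at_step(10, 100, 10, 0.03)  # == 0.03
#' @export
lr_at_step <- function(step, total_steps, warmup_steps, base_lr) {
  if (any(step < 0 | step >= total_steps)) stopf("step out of range")
  if (warmup_steps >= total_steps) stopf("warmup_steps must be below total_steps")
  ifelse(step < warmup_steps,
         base_lr * step / max(warmup_steps, 1),
         base_lr * (1 + cos(pi * (step - warmup_steps) / (total_steps - warmup_steps))) / 2)
}

#' Stratified k-fold assignment
#'
#' Partitions indices into k validation folds preserving per-class
#' proportions within one sample, while balancing total fold sizes: per-class
#' remainders are assigned to the folds currently holding the fewest samples,
#' so a 1296/319 two-class corpus splits into five folds of exactly 323
#' samples holding 63--64 minority cases each. Deterministic for a fixed
#' seed.
#'
#' @param labels integer class labels.
#' @param k fold count; every class must have at least k members.
#' @param seed RNG seed for the within-class shuffles.
#' @return List of k `fold_split` objects with fields `fold_id`,
#'   `train_indices`, `val_indices` (1-based).
#' @export
stratified_kfold <- function(labels, k = 5, seed = 0) {
  classes <- sort(unique(labels))
  counts <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  if (any(counts < k)) stopf("every class needs at least k = %d members", k)
  assign_fold <- integer(length(labels))
  load <- numeric(k)
  with_seed(seed, {
    for (cl in classes[order(-counts)]) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      base <- n %/% k; extra <- n %% k
      sizes <- rep(base, k)
      if (extra > 0) sizes[order(load, sample(k))[seq_len(extra)]] <- base + 1
      f <- rep(seq_len(k), times = sizes)
      assign_fold[idx] <- f
      load <- load + sizes
    }
  })
  all_idx <- seq_along(labels)
  lapply(seq_len(k), function(i) {
    structure(list(fold_id = i,
                   train_indices = all_idx[assign_fold != i],
                   val_indices = all_idx[assign_fold == i]),
              class = "fold_split")
  })
}

#' Data augmentation
#'
#' Training samples receive random horizontal and vertical flips (probability
#' 0.5 each) followed by normalization; validation samples are only
#' normalized. Deterministic for a fixed seed. The geometric transform is
#' applied to the pixel raster; the normalized tensor is attached as the
#' `"tensor"` attribute.
#'
#' @param image a [sketch_image()].
#' @param split `"train"` or `"val"`.
#' @param rng_seed seed controlling the flip draws.
#' @param mean,sd normalization constants (see [normalize_pixels()]).
#' @return The augmented [sketch_image()] with the normalized array in
#'   `attr(, "tensor")`.
#' @export
augment <- function(image, split = c("train", "val"), rng_seed = 0,
                    mean = c(0.485, 0.456, 0.406), sd = c(0.229, 0.224, 0.225)) {
  split <- match.arg(split)
  stopifnot(inherits(image, "sketch_image"))
  px <- image$pixels
  if (split == "train") {
    fl <- with_seed(rng_seed, stats::runif(2) < 0.5)
    px <- flip_array(px, horizontal = fl[1], vertical = fl[2])
  }
  out <- sketch_image(px, background = image$background, label = image$label,
                      source_size = image$source_size)
  attr(out, "tensor") <- normalize_pixels(px, mean, sd)
  out
}

# ---- optimizer ------------------------------------------------------------

sgd_step <- function(params, grads, vel, lr, momentum, weight_decay = 0) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    v <- momentum * (vel[[nm]] %||% (g * 0)) - lr * g
    vel[[nm]] <- v
    params[[nm]] <- params[[nm]] + v
  }
  list(params = params, vel = vel)
}

# ---- datasets -------------------------------------------------------------

#' Labeled sketch dataset container
#'
#' @param images list of [sketch_image()] objects.
#' @param labels integer class labels (0-based), one per image.
#' @param num_class total class count (default: `max(labels) + 1`).
#' @param split optional character vector (`"train"`/`"val"`/`"test"`).
#' @return An object of class `sketch_dataset`.
#' @export
sketch_dataset <- function(images, labels, num_class = NULL, split = NULL) {
  if (length(images) != length(labels)) stopf("images and labels disagree in length")
  labels <- as.integer(labels)
  structure(list(images = images, labels = labels,
                 num_class = as.integer(num_class %||% (max(labels) + 1L)),
                 split = split),
            class = "sketch_dataset")
}

#' @export
print.sketch_dataset <- function(x, ...) {
  cat(sprintf("<sketch_dataset: %d images, %d classes>\n", length(x$images), x$num_class))
  tab <- table(x$labels)
  cat("  per class:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' @export
length.sketch_dataset <- function(x) length(x$images)

# Resize + (conditionally invert) every image once; flips and normalization
# happen per epoch on the cached 0-255 arrays.
preprocess_dataset <- function(dataset, config) {
  lapply(dataset$images, function(im) {
    px <- im$pixels
    if (im$background == "black") px <- 255 - px
    if (any(dim(px)[1:2] != config$input_side))
      px <- clamp(resize_bilinear(px, config$input_side, config$input_side), 0, 255)
    px
  })
}

# One training run over fixed train/val index sets. Returns final model,
# per-epoch history, and the best (highest val accuracy) epoch metrics.
train_loop <- function(model, cache_px, labels, idx_train, idx_val, tc,
                       run_seed, log_fn = NULL, positive_class = 1L) {
  cfg <- model$config
  steps_per_epoch <- max(1L, ceiling(length(idx_train) / tc$batch_size))
  total_steps <- steps_per_epoch * tc$epochs
  # degenerate short runs: warmup must leave at least one decay step
  warmup_steps <- min(round(tc$warmup_epochs * steps_per_epoch), total_steps - 1L)
  vel <- list()
  step <- 0L
  history <- list()
  best <- NULL
  norm_one <- function(px) normalize_pixels(px, cfg$norm_mean, cfg$norm_sd)
  for (epoch in seq_len(tc$epochs)) {
    ord <- with_seed(derive_seed(run_seed, 7, epoch), sample(idx_train))
    ep_loss <- 0; nb <- 0
    for (start in seq(1, length(ord), by = tc$batch_size)) {
      take <- ord[start:min(start + tc$batch_size - 1, length(ord))]
      xg <- array(0, c(cfg$input_side, cfg$input_side, 3, length(take)))
      for (j in seq_along(take)) {
        px <- cache_px[[take[j]]]
        fl <- with_seed(derive_seed(run_seed, 11, epoch, take[j]), stats::runif(2) < 0.5)
        px <- flip_array(px, horizontal = tc$hflip && fl[1], vertical = tc$vflip && fl[2])
        xg[, , , j] <- norm_one(px)
      }
      lr <- lr_at_step(step, total_steps, warmup_steps, tc$base_lr)
      gr <- fbanet_grad(model, xg, labels[take], train = TRUE)
      model$buffers <- gr$buffers
      upd <- sgd_step(model$params, gr$grads, vel, lr, tc$momentum, tc$weight_decay)
      model$params <- upd$params; vel <- upd$vel
      ep_loss <- ep_loss + gr$loss; nb <- nb + 1
      step <- step + 1L
    }
    ev <- evaluate_split(model, cache_px, labels, idx_val, positive_class)
    rec <- c(list(epoch = epoch, lr = lr_at_step(step - 1L, total_steps, warmup_steps, tc$base_lr),
                  train_loss = ep_loss / nb, val_loss = ev$loss), unclass(ev$metrics)[1:4])
    history[[epoch]] <- rec
    if (!is.null(log_fn)) log_fn(rec)
    if (is.null(best) || ev$metrics$accuracy > best$metrics$accuracy)
      best <- list(epoch = epoch, metrics = ev$metrics, confusion = ev$confusion,
                   loss = ev$loss)
  }
  list(model = model, best = best,
       history = do.call(rbind, lapply(history, function(r) as.data.frame(r))))
}

# Validation-mode evaluation of index subset; returns loss + metrics.
evaluate_split <- function(model, cache_px, labels, idx, positive_class = 1L) {
  cfg <- model$config
  logits <- matrix(0, length(idx), cfg$num_class)
  bs <- 32L
  for (start in seq(1, length(idx), by = bs)) {
    take <- idx[start:min(start + bs - 1, length(idx))]
    xg <- array(0, c(cfg$input_side, cfg$input_side, 3, length(take)))
    for (j in seq_along(take))
      xg[, , , j] <- normalize_pixels(cache_px[[take[j]]], cfg$norm_mean, cfg$norm_sd)
    logits[start:(start + length(take) - 1), ] <-
      fbanet_forward(model, xg, train = FALSE)$logits
  }
  pred <- max.col(logits, ties.method = "first") - 1L
  truth <- labels[idx]
  ce <- cross_entropy_logits(logits, truth)
  if (cfg$num_class == 2) {
    cm <- confusion(pred, truth, positive_class)
    metrics <- suppressWarnings(compute_metrics(cm))   # undefined ratios flagged in-object
  } else {
    cm <- NULL
    acc <- mean(pred == truth)
    metrics <- structure(list(accuracy = acc, precision = acc, recall = acc, f1 = acc,
                              undefined = character(0)), class = "fbanet_metrics")
  }
  list(loss = ce$loss, metrics = metrics, confusion = cm, predictions = pred)
}

#' Fine-tune under stratified k-fold cross-validation
#'
#' For each fold the model is initialized (from a pretrained checkpoint when
#' given, otherwise fresh), trained with SGD + momentum under the
#' warmup-cosine schedule and cross-entropy loss with flip augmentation, and
#' evaluated on the fold's validation split after every epoch. No parameters
#' are frozen. The best epoch per fold (highest validation accuracy) is
#' reported, with average and maximum aggregation across folds.
#'
#' @param model_config an [fbanet_config()] (must have `num_class` matching
#'   the dataset) or a prebuilt [fbanet()] model used as the starting point.
#' @param train_config a [train_config()] with `phase = "finetune"`.
#' @param dataset a labeled [sketch_dataset()].
#' @param checkpoint optional path to a pretrained checkpoint (its head is
#'   transferred to the dataset's class count).
#' @param positive_class class id treated as positive in the confusion-matrix
#'   metrics (default 1, the minority "depressed" class).
#' @param log_fn optional callback receiving one record per epoch.
#' @return An object of class `fbanet_cv`: per-fold reports, aggregate
#'   average/max metrics, and the last fold's fitted model.
#' @export
run_finetune <- function(model_config, train_config = NULL, dataset,
                         checkpoint = NULL, positive_class = 1L, log_fn = NULL) {
  tc <- train_config %||% train_config("finetune")
  stopifnot(inherits(dataset, "sketch_dataset"))
  base_model <- if (inherits(model_config, "fbanet")) model_config
    else if (!is.null(checkpoint)) {
      if (!file.exists(checkpoint)) stopf("checkpoint not found: %s", checkpoint)
      transfer_head(load_checkpoint(checkpoint), dataset$num_class,
                    seed = derive_seed(tc$seed, 3))
    } else NULL
  cfg <- if (is.null(base_model)) model_config else base_model$config
  stopifnot(inherits(cfg, "fbanet_config"))
  if (cfg$num_class != dataset$num_class) stopf("config num_class != dataset classes")
  folds <- stratified_kfold(dataset$labels, tc$folds, seed = tc$seed)
  cache_px <- preprocess_dataset(dataset, cfg)
  reports <- vector("list", length(folds))
  model <- NULL
  for (f in seq_along(folds)) {
    model <- if (!is.null(base_model)) base_model else {
      cfg_f <- cfg; cfg_f$seed <- derive_seed(tc$seed, 5, f)
      fbanet(cfg_f)
    }
    fit <- train_loop(model, cache_px, dataset$labels,
                      folds[[f]]$train_indices, folds[[f]]$val_indices, tc,
                      run_seed = derive_seed(tc$seed, 13, f),
                      log_fn = if (is.null(log_fn)) NULL else function(rec)
                        log_fn(c(list(fold = f), rec)),
                      positive_class = positive_class)
    model <- fit$model
    reports[[f]] <- structure(
      list(fold_id = f, best_epoch = fit$best$epoch, metrics = fit$best$metrics,
           confusion = fit$best$confusion, val_loss = fit$best$loss,
           history = fit$history),
      class = "fold_report")
  }
  agg <- aggregate_folds(lapply(reports, `[[`, "metrics"))
  structure(list(folds = reports, average = agg$average, max = agg$max,
                 model = model, config = cfg, train_config = tc),
            class = "fbanet_cv")
}

#' @export
print.fold_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("fold %d (best epoch %d): acc %.4f  prec %.4f  rec %.4f  f1 %.4f\n",
              x$fold_id, x$best_epoch, m$accuracy, m$precision, m$recall, m$f1))
  invisible(x)
}

#' @export
print.fbanet_cv <- function(x, ...) {
  cat(sprintf("Stratified %d-fold cross-validation\n", length(x$folds)))
  for (f in x$folds) print(f)
  cat(sprintf("average: acc %.4f  prec %.4f  rec %.4f  f1 %.4f\n",
              x$average$accuracy, x$average$precision, x$average$recall, x$average$f1))
  cat(sprintf("max:     acc %.4f  prec %.4f  rec %.4f  f1 %.4f\n",
              x$max$accuracy, x$max$precision, x$max$recall, x$max$f1))
  invisible(x)
}

#' @export
summary.fbanet_cv <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Supervised pre-training on a many-class sketch corpus
#'
#' Trains from scratch on a labeled multi-class dataset. Black-background
#' images are color-inverted to the white-background polarity before entering
#' the model. Returns the trained model with its per-epoch history; save with
#' [save_checkpoint()] for later transfer.
#'
#' @param model_config an [fbanet_config()].
#' @param train_config a [train_config()] with `phase = "pretrain"`.
#' @param dataset a labeled [sketch_dataset()]; images carry their background
#'   polarity. If the dataset has a `split` field, `"val"` entries form the
#'   validation set; otherwise a seeded 90/10 split is used.
#' @param log_fn optional per-epoch callback.
#' @return List of class `fbanet_pretrain`: `model`, `history`.
#' @export
run_pretrain <- function(model_config, train_config = NULL, dataset, log_fn = NULL) {
  tc <- train_config %||% train_config("pretrain")
  stopifnot(inherits(model_config, "fbanet_config"), inherits(dataset, "sketch_dataset"))
  if (model_config$num_class != dataset$num_class) stopf("config num_class != dataset classes")
  n <- length(dataset$images)
  if (!is.null(dataset$split)) {
    idx_val <- which(dataset$split == "val")
    idx_train <- which(dataset$split == "train")
    if (length(idx_train) == 0) idx_train <- setdiff(seq_len(n), idx_val)
  } else {
    idx_val <- with_seed(derive_seed(tc$seed, 17), sample(n, max(1, round(0.1 * n))))
    idx_train <- setdiff(seq_len(n), idx_val)
  }
  cache_px <- preprocess_dataset(dataset, model_config)  # inverts black backgrounds
  model <- fbanet(model_config)
  fit <- train_loop(model, cache_px, dataset$labels, idx_train, idx_val, tc,
                    run_seed = derive_seed(tc$seed, 19), log_fn = log_fn)
  structure(list(model = fit$model, history = fit$history, best = fit$best),
            class = "fbanet_pretrain")
}

#' @export
print.fbanet_pretrain <- function(x, ...) {
  cat(sprintf("Pretrained model: %d epochs, final val accuracy %.4f\n",
              nrow(x$history), x$history$accuracy[nrow(x$history)]))
  invisible(x)
}

#' Evaluate a model on a labeled dataset
#'
#' @param model an [fbanet()] model.
#' @param dataset a labeled [sketch_dataset()].
#' @param positive_class positive class id for binary metrics.
#' @return List with `metrics`, `confusion` (binary tasks), `loss`,
#'   `predictions`.
#' @export
evaluate_model <- function(model, dataset, positive_class = 1L) {
  stopifnot(inherits(model, "fbanet"), inherits(dataset, "sketch_dataset"))
  cache_px <- preprocess_dataset(dataset, model$config)
  evaluate_split(model, cache_px, dataset$labels, seq_along(dataset$images),
                 positive_class)
}
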