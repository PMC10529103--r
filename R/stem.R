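# Convolutional stems. A stem is a declarative list of primitive layers
# (conv / bn / relu / maxpool / residual bottleneck block); a small generic
# engine derives parameter shapes, initializes weights, and runs forward and
# backward passes. Stems are pluggable via ModelConfig$stem:
#   "resnet50" - the full 50-layer residual backbone without its classifier
#                (c = 2048, 32x downsampling), the default for full-scale runs;
#   "tiny"     - a 3-convolution stem (c = 32, 8x downsampling) for desk-scale
#                experiments and tests.

conv_l <- function(k, stride, pad, cin, cout, bias = TRUE)
  list(type = "conv", k = k, stride = stride, pad = pad, cin = cin, cout = cout, bias = bias)
bn_l <- function(c) list(type = "bn", c = c)
relu_l <- function() list(type = "relu")
maxpool_l <- function(k = 3, stride = 2, pad = 1) list(type = "maxpool", k = k, stride = stride, pad = pad)
block_l <- function(main, shortcut = NULL) list(type = "block", main = main, shortcut = shortcut)

bottleneck <- function(cin, cmid, cout, stride = 1) {
  main <- list(conv_l(1, 1, 0, cin, cmid, bias = FALSE), bn_l(cmid), relu_l(),
               conv_l(3, stride, 1, cmid, cmid, bias = FALSE), bn_l(cmid), relu_l(),
               conv_l(1, 1, 0, cmid, cout, bias = FALSE), bn_l(cout))
  shortcut <- if (cin != cout || stride != 1)
    list(conv_l(1, stride, 0, cin, cout, bias = FALSE), bn_l(cout)) else NULL
  block_l(main, shortcut)
}

resnet_stage <- function(cin, cmid, cout, n, stride) {
  c(list(bottleneck(cin, cmid, cout, stride)),
    lapply(seq_len(n - 1), function(i) bottleneck(cout, cmid, cout, 1)))
}

stem_spec <- function(stem_id) {
  switch(stem_id,
    tiny = list(
      layers = list(conv_l(3, 2, 1, 3, 8), relu_l(),
                    conv_l(3, 2, 1, 8, 16), relu_l(),
                    conv_l(3, 2, 1, 16, 32), relu_l()),
      out_channels = 32L, downsample = 8L),
    resnet50 = list(
      layers = c(list(conv_l(7, 2, 3, 3, 64, bias = FALSE), bn_l(64), relu_l(), maxpool_l()),
                 resnet_stage(64, 64, 256, 3, 1),
                 resnet_stage(256, 128, 512, 4, 2),
                 resnet_stage(512, 256, 1024, 6, 2),
                 resnet_stage(1024, 512, 2048, 3, 2)),
      out_channels = 2048L, downsample = 32L),
    stopf("unknown stem '%s' (available: tiny, resnet50)", stem_id)
  )
}

# ---- generic layer-sequence machinery -------------------------------------

seq_shapes <- function(layers, prefix) {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]; p <- paste0(prefix, ".", i)
    if (l$type == "conv") {
      out[[paste0(p, ".W")]] <- c(l$k * l$k * l$cin, l$cout)
      if (l$bias) out[[paste0(p, ".b")]] <- l$cout
    } else if (l$type == "bn") {
      out[[paste0(p, ".g")]] <- l$c
      out[[paste0(p, ".b")]] <- l$c
    } else if (l$type == "block") {
      out <- c(out, seq_shapes(l$main, paste0(p, ".m")))
      if (!is.null(l$shortcut)) out <- c(out, seq_shapes(l$shortcut, paste0(p, ".s")))
    }
  }
  out
}

seq_init <- function(layers, prefix) {
  params <- list(); buffers <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]; p <- paste0(prefix, ".", i)
    if (l$type == "conv") {
      fan_in <- l$k * l$k * l$cin
      params[[paste0(p, ".W")]] <-
        matrix(stats::rnorm(fan_in * l$cout, sd = sqrt(2 / fan_in)), fan_in, l$cout)
      if (l$bias) params[[paste0(p, ".b")]] <- numeric(l$cout)
    } else if (l$type == "bn") {
      params[[paste0(p, ".g")]] <- rep(1, l$c)
      params[[paste0(p, ".b")]] <- numeric(l$c)
      buffers[[paste0(p, ".rm")]] <- numeric(l$c)
      buffers[[paste0(p, ".rv")]] <- rep(1, l$c)
    } else if (l$type == "block") {
      m <- seq_init(l$main, paste0(p, ".m"))
      params <- c(params, m$params); buffers <- c(buffers, m$buffers)
      if (!is.null(l$shortcut)) {
        s <- seq_init(l$shortcut, paste0(p, ".s"))
        params <- c(params, s$params); buffers <- c(buffers, s$buffers)
      }
    }
  }
  list(params = params, buffers = buffers)
}

seq_fwd <- function(layers, prefix, params, buffers, x, train) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]; p <- paste0(prefix, ".", i)
    if (l$type == "conv") {
      f <- conv2d_fwd(x, params[[paste0(p, ".W")]],
                      if (l$bias) params[[paste0(p, ".b")]] else NULL, l$stride, l$pad)
      x <- f$y; caches[[i]] <- f$cache
    } else if (l$type == "bn") {
      f <- bnorm_fwd(x, params[[paste0(p, ".g")]], params[[paste0(p, ".b")]],
                     buffers[[paste0(p, ".rm")]], buffers[[paste0(p, ".rv")]], train)
      x <- f$y; caches[[i]] <- f$cache
      buffers[[paste0(p, ".rm")]] <- f$rm; buffers[[paste0(p, ".rv")]] <- f$rv
    } else if (l$type == "relu") {
      f <- relu_fwd(x); x <- f$y; caches[[i]] <- f$cache
    } else if (l$type == "maxpool") {
      f <- maxpool_fwd(x, l$k, l$stride, l$pad); x <- f$y; caches[[i]] <- f$cache
    } else if (l$type == "block") {
      fm <- seq_fwd(l$main, paste0(p, ".m"), params, buffers, x, train)
      buffers <- fm$buffers
      if (!is.null(l$shortcut)) {
        fs <- seq_fwd(l$shortcut, paste0(p, ".s"), params, buffers, x, train)
        buffers <- fs$buffers
        s_out <- fs$y; s_cache <- fs$caches
      } else { s_out <- x; s_cache <- NULL }
      pre <- fm$y + s_out
      r <- relu_fwd(pre)
      caches[[i]] <- list(main = fm$caches, shortcut = s_cache, relu = r$cache)
      x <- r$y
    }
  }
  list(y = x, caches = caches, buffers = buffers)
}

seq_bwd <- function(layers, prefix, params, caches, dy, need_input_grad = TRUE) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]; p <- paste0(prefix, ".", i)
    if (l$type == "conv") {
      g <- conv2d_bwd(dy, caches[[i]], need_dx = need_input_grad || i > 1)
      grads[[paste0(p, ".W")]] <- g$dW
      if (l$bias) grads[[paste0(p, ".b")]] <- g$db
      dy <- g$dx
    } else if (l$type == "bn") {
      g <- bnorm_bwd(dy, caches[[i]])
      grads[[paste0(p, ".g")]] <- g$dg
      grads[[paste0(p, ".b")]] <- g$db
      dy <- g$dx
    } else if (l$type == "relu") {
      dy <- relu_bwd(dy, caches[[i]])
    } else if (l$type == "maxpool") {
      dy <- maxpool_bwd(dy, caches[[i]])
    } else if (l$type == "block") {
      dpre <- relu_bwd(dy, caches[[i]]$relu)
      gm <- seq_bwd(l$main, paste0(p, ".m"), params, caches[[i]]$main, dpre)
      grads <- c(grads, gm$grads)
      dx <- gm$dx
      if (!is.null(l$shortcut)) {
        gs <- seq_bwd(l$shortcut, paste0(p, ".s"), params, caches[[i]]$shortcut, dpre)
        grads <- c(grads, gs$grads)
        dx <- dx + gs$dx
      } else {
        dx <- dx + dpre
      }
      dy <- dx
    }
  }
  list(dx = dy, grads = grads)
}

#' Run the shared convolutional stem over a batch of sketches
#'
#' Applies the model's stem (shared between local patches and the global
#' image) to a batch of equally sized inputs and returns one feature tensor
#' per image. Inputs must already be normalized to the stem's expected
#' statistics (see [normalize_pixels()]).
#'
#' @param images list of normalized `(side, side, 3)` arrays, or a single such
#'   array, or a `(side, side, 3, n)` batch array.
#' @param model a fitted or freshly built [fbanet()] model (its stem weights
#'   are used).
#' @return List of `(h, w, c)` feature arrays, one per input image.
#' @export
stem_forward <- function(images, model) {
  stopifnot(inherits(model, "fbanet"))
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  if (is.list(images)) {
    side <- dim(images[[1]])[1]
    if (any(vapply(images, function(i) any(dim(i)[1:2] != side), logical(1))))
      stopf("all stem inputs must share the same side length")
    x <- array(unlist(images, use.names = FALSE), c(dim(images[[1]]), length(images)))
  } else x <- images
  spec <- stem_spec(model$config$stem)
  f <- seq_fwd(spec$layers, "stem", model$params, model$buffers, x, train = FALSE)
  n <- dim(f$y)[4]
  lapply(seq_len(n), function(i) f$y[, , , i, drop = TRUE])
}
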