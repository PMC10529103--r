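#' Model configuration
#'
#' Collects every architecture hyperparameter of the feature-enhanced
#' bi-level attention network, including the ablation switches. The named
#' scales correspond to the depth of the self-attention stack: small = 6,
#' base = 12, large = 18 layers.
#'
#' @param num_patches number of overlapping local patches, 5 or 9.
#' @param layers depth L of the self-attention stack (6/12/18 for the named
#'   small/base/large scales; any positive value is accepted for reduced
#'   experiments).
#' @param heads requested attention head count n (default 8). If the token
#'   width `d = h*w` is not divisible, the largest divisor of `d` below it is
#'   used at run time; parameter counts are unaffected.
#' @param adjusted_channels N, the channel count after the 1x1
#'   channel-adjustment convolution; this is also the token count of the
#'   attention stack. Default 256.
#' @param mlp_ratio hidden-width expansion of the transformer MLP (default 4).
#' @param num_class number of output classes (2 for the depression screening
#'   task, 345 for the many-class pre-training corpus).
#' @param input_side model input resolution in pixels (default 224).
#' @param stem convolutional stem id: `"resnet50"` (default) or `"tiny"`.
#' @param sigma patch side fraction; defaults to 0.6 for 5 patches, 0.4 for 9.
#' @param feature_enhance,triplet_attention,self_attention component switches
#'   for ablation studies. With `feature_enhance = FALSE` the local-patch
#'   branch is bypassed and the global features alone pass through the 1x1
#'   adjustment. With both attention switches off the model degenerates to
#'   enhanced features straight into the head.
#' @param extra_prenorm apply an extra LayerNorm before each attention
#'   sub-block (off by default: the attention residual is applied to the raw
#'   sequence, with LayerNorm only at embedding and inside the MLP
#'   sub-block).
#' @param norm_mean,norm_sd channel normalization constants (ImageNet
#'   defaults).
#' @param seed seed used for weight initialization.
#' @return An object of class `fbanet_config`.
#' @examples
#' cfg <- fbanet_config(num_patches = 5, layers = 6, stem = "tiny",
#'                      input_side = 64, adjusted_channels = 16)
#' count_trainable_parameters(cfg)
#' @export
fbanet_config <- function(num_patches = 5, layers = 12, heads = 8,
                          adjusted_channels = 256, mlp_ratio = 4, num_class = 2,
                          input_side = 224, stem = "resnet50", sigma = NULL,
                          feature_enhance = TRUE, triplet_attention = TRUE,
                          self_attention = TRUE, extra_prenorm = FALSE,
                          norm_mean = c(0.485, 0.456, 0.406),
                          norm_sd = c(0.229, 0.224, 0.225), seed = 0) {
  if (!num_patches %in% c(5, 9)) stopf("num_patches must be 5 or 9")
  if (!is_count(layers) || layers < 1) stopf("layers must be a positive integer")
  if (!is_count(heads) || heads < 1) stopf("heads must be a positive integer")
  if (!is_count(num_class) || num_class < 2) stopf("num_class must be >= 2")
  if (is.null(sigma)) sigma <- if (num_patches == 5) 0.6 else 0.4
  spec <- stem_spec(stem)
  if (input_side %% spec$downsample != 0)
    stopf("input_side must be a multiple of the stem downsampling factor (%d)", spec$downsample)
  cfg <- structure(
    list(num_patches = as.integer(num_patches), sigma = sigma,
         layers = as.integer(layers), heads = as.integer(heads),
         adjusted_channels = as.integer(adjusted_channels),
         mlp_ratio = mlp_ratio, num_class = as.integer(num_class),
         input_side = as.integer(input_side), stem = stem,
         feature_enhance = isTRUE(feature_enhance),
         triplet_attention = isTRUE(triplet_attention),
         self_attention = isTRUE(self_attention),
         extra_prenorm = isTRUE(extra_prenorm),
         norm_mean = norm_mean, norm_sd = norm_sd, seed = as.integer(seed)),
    class = "fbanet_config")
  cfg
}

#' @export
print.fbanet_config <- function(x, ...) {
  scale <- c(`6` = "small", `12` = "base", `18` = "large")[as.character(x$layers)]
  cat(sprintf("<fbanet_config %s: P = %d, L = %d, N = %d, stem = %s, %d classes, %d px>\n",
              if (is.na(scale)) "custom" else scale, x$num_patches, x$layers,
              x$adjusted_channels, x$stem, x$num_class, x$input_side))
  flags <- c(feature_enhance = x$feature_enhance, triplet = x$triplet_attention,
             self_attention = x$self_attention)
  if (!all(flags)) cat("  ablation: ", paste(names(flags)[!flags], "off"), "\n")
  invisible(x)
}

# Derived geometry: stem output channels c, spatial side, token width d,
# fused channel count M.
config_geometry <- function(config) {
  spec <- stem_spec(config$stem)
  side <- config$input_side %/% spec$downsample
  d <- side * side
  N <- config$adjusted_channels
  n_ops <- config$self_attention + config$triplet_attention
  M <- if (n_ops == 0) N else N * n_ops + N
  list(c = spec$out_channels, h = side, w = side, d = d, N = N, M = M,
       degenerate = n_ops == 0)
}

#' Parameter shapes of the assembled model
#'
#' @param config an [fbanet_config()].
#' @return Named list mapping parameter names to dimension vectors.
#' @export
fbanet_param_shapes <- function(config) {
  g <- config_geometry(config)
  spec <- stem_spec(config$stem)
  shapes <- seq_shapes(spec$layers, "stem")
  cin <- if (config$feature_enhance) 2 * g$c else g$c
  shapes[["adjust.W"]] <- c(cin, g$N)
  shapes[["adjust.b"]] <- g$N
  if (config$self_attention) {
    shapes[["epos"]] <- c(g$N, g$d)
    shapes[["ln0.g"]] <- g$d
    shapes[["ln0.b"]] <- g$d
    for (l in seq_len(config$layers)) {
      p <- paste0("attn.", l, ".")
      if (config$extra_prenorm) {
        shapes[[paste0(p, "pre.g")]] <- g$d
        shapes[[paste0(p, "pre.b")]] <- g$d
      }
      for (w in c("Wq", "Wk", "Wv", "Wo")) shapes[[paste0(p, "mhsa.", w)]] <- c(g$d, g$d)
      dh <- g$d * config$mlp_ratio
      shapes[[paste0(p, "mlp.ln.g")]] <- g$d
      shapes[[paste0(p, "mlp.ln.b")]] <- g$d
      shapes[[paste0(p, "mlp.fc1.W")]] <- c(g$d, dh)
      shapes[[paste0(p, "mlp.fc1.b")]] <- dh
      shapes[[paste0(p, "mlp.fc2.W")]] <- c(dh, g$d)
      shapes[[paste0(p, "mlp.fc2.b")]] <- g$d
    }
  }
  if (config$triplet_attention) {
    for (j in 1:3) {
      shapes[[paste0("trip.", j, ".W")]] <- c(98, 1)
      shapes[[paste0("trip.", j, ".bn.g")]] <- 1
      shapes[[paste0("trip.", j, ".bn.b")]] <- 1
    }
  }
  if (!g$degenerate) {
    shapes[["gproj.W"]] <- c(g$c, g$N)
    shapes[["gproj.b"]] <- g$N
  }
  shapes[["head.W"]] <- c(g$M, g$N)
  shapes[["head.b"]] <- g$N
  shapes[["fc.W"]] <- c(g$N, config$num_class)
  shapes[["fc.b"]] <- config$num_class
  shapes
}

#' Count the learnable scalars of a model configuration
#'
#' Exact, deterministic count of trainable parameters in the assembled
#' network. Structural properties: the count is invariant to the number of
#' patches (the stem is shared, so patches add no weights) and increases by a
#' constant amount per attention layer.
#'
#' @param config an [fbanet_config()] or a built [fbanet()] model.
#' @return Integer-valued numeric, the number of trainable scalars.
#' @examples
#' p6 <- count_trainable_parameters(fbanet_config(layers = 6, stem = "tiny",
#'                                                input_side = 64))
#' @export
count_trainable_parameters <- function(config) {
  if (inherits(config, "fbanet")) config <- config$config
  stopifnot(inherits(config, "fbanet_config"))
  sum(vapply(fbanet_param_shapes(config), prod, numeric(1)))
}

#' Build a feature-enhanced bi-level attention network
#'
#' Initializes all weights from `config$seed`. The returned object holds the
#' flat named parameter list, non-trainable buffers (running normalization
#' moments), and the configuration; it is the input to [predict.fbanet()],
#' [run_finetune()], [run_pretrain()] and [grad_cam()].
#'
#' @param config an [fbanet_config()].
#' @return An object of class `fbanet` with fields `config`, `params`,
#'   `buffers`.
#' @export
fbanet <- function(config = fbanet_config()) {
  stopifnot(inherits(config, "fbanet_config"))
  g <- config_geometry(config)
  spec <- stem_spec(config$stem)
  model <- with_seed(config$seed, {
    st <- seq_init(spec$layers, "stem")
    params <- st$params; buffers <- st$buffers
    shapes <- fbanet_param_shapes(config)
    for (nm in setdiff(names(shapes), names(params))) {
      sh <- shapes[[nm]]
      n <- prod(sh)
      val <- if (grepl("(ln|bn|pre)\\.g$|ln0\\.g$", nm)) rep(1, n)
        else if (grepl("\\.b$", nm)) numeric(n)
        else if (nm == "epos") stats::rnorm(n, sd = 0.02)
        else if (nm == "fc.W") stats::rnorm(n, sd = 0.01)
        else if (grepl("^attn\\.", nm)) stats::rnorm(n, sd = 0.02)
        else stats::rnorm(n, sd = sqrt(2 / sh[1]))
      params[[nm]] <- if (length(sh) == 2) matrix(val, sh[1], sh[2]) else val
    }
    if (config$triplet_attention)
      for (j in 1:3) {
        buffers[[paste0("trip.", j, ".rm")]] <- 0
        buffers[[paste0("trip.", j, ".rv")]] <- 1
      }
    list(params = params, buffers = buffers)
  })
  structure(list(config = config, params = model$params, buffers = model$buffers),
            class = "fbanet")
}

#' @export
print.fbanet <- function(x, ...) {
  g <- config_geometry(x$config)
  cat("Feature-enhanced bi-level attention network\n")
  print(x$config)
  cat(sprintf("  stem output: %d x %d x %d; tokens: %d x %d; fused channels: %d\n",
              g$h, g$w, g$c, g$N, g$d, g$M))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
summary.fbanet <- function(object, ...) {
  print(object)
  shapes <- fbanet_param_shapes(object$config)
  grp <- sub("^(stem|attn|trip)\\..*", "\\1", names(shapes))
  grp[!grp %in% c("stem", "attn", "trip")] <- names(shapes)[!grp %in% c("stem", "attn", "trip")]
  tot <- tapply(vapply(shapes, prod, numeric(1)), grp, sum)
  cat("\nParameters by group:\n")
  for (nm in names(tot)) cat(sprintf("  %-12s %12s\n", nm, format(tot[[nm]], big.mark = ",")))
  invisible(object)
}

# ---- forward / backward ----------------------------------------------------

# Forward pass over a batch of normalized global images xg (side, side, 3, B).
# Returns logits (B x num_class) and a cache sufficient for the backward
# pass; `taps` names intermediate activations to record per sample
# ("fw", "fusion", "gproj", "head_conv", "stem_global").
fbanet_forward <- function(model, xg, train = FALSE, taps = character()) {
  cfg <- model$config
  g <- config_geometry(cfg)
  s <- cfg$input_side
  B <- dim(xg)[4]
  P <- if (cfg$feature_enhance) cfg$num_patches else 0L
  kper <- P + 1L
  layout <- if (P > 0) compute_patch_layout(s, s, cfg$num_patches, cfg$sigma) else NULL
  xin <- array(0, c(s, s, 3, B * kper))
  for (b in seq_len(B)) {
    base <- (b - 1) * kper
    if (P > 0) {
      pats <- crop_patches_array(xg[, , , b, drop = TRUE], layout, s)
      for (i in seq_len(P)) xin[, , , base + i] <- pats[[i]]
    }
    xin[, , , base + kper] <- xg[, , , b]
  }
  spec <- stem_spec(cfg$stem)
  st <- seq_fwd(spec$layers, "stem", model$params, model$buffers, xin, train)
  buffers <- st$buffers
  feat <- st$y                       # (h, w, c, B*kper)
  hw <- g$h * g$w
  pm <- model$params
  cs <- list(tap = list())
  gidx <- seq_len(B) * kper
  Fg_all <- array(feat[, , , gidx], c(g$h, g$w, g$c, B))
  if (P > 0) {
    Fhat <- array(0, c(g$h, g$w, g$c, B))
    for (i in seq_len(P))
      Fhat <- Fhat + array(feat[, , , (seq_len(B) - 1) * kper + i], dim(Fhat))
    Fhat <- Fhat / P
    FLG <- array(0, c(g$h, g$w, 2 * g$c, B))
    FLG[, , seq_len(g$c), ] <- Fhat
    FLG[, , g$c + seq_len(g$c), ] <- Fg_all
  } else {
    FLG <- Fg_all
  }
  cin <- dim(FLG)[3]
  # rows ordered (pixel, sample); columns = channels
  x2 <- matrix(aperm(FLG, c(1, 2, 4, 3)), hw * B, cin)
  fwm <- x2 %*% pm$adjust.W
  fwm <- sweep(fwm, 2, pm$adjust.b, `+`)                # (hw*B) x N
  Fw_arr <- aperm(array(fwm, c(g$h, g$w, B, g$N)), c(1, 2, 4, 3))
  cs$x2 <- x2
  if ("fw" %in% taps) cs$tap$fw <- Fw_arr
  if ("stem_global" %in% taps) cs$tap$stem_global <- Fg_all
  ops <- list()
  # -- self-attention path: tokens stacked (B*N) x d, sample-major blocks
  if (cfg$self_attention) {
    X <- matrix(aperm(array(fwm, c(hw, B, g$N)), c(3, 2, 1)), g$N * B, hw)
    X <- X + pm$epos[rep(seq_len(g$N), B), , drop = FALSE]
    ln0 <- layernorm_fwd(X, pm$ln0.g, pm$ln0.b)
    X <- ln0$y
    lay_caches <- vector("list", cfg$layers)
    for (l in seq_len(cfg$layers)) {
      p <- paste0("attn.", l, ".")
      lc <- list()
      wts <- list(Wq = pm[[paste0(p, "mhsa.Wq")]], Wk = pm[[paste0(p, "mhsa.Wk")]],
                  Wv = pm[[paste0(p, "mhsa.Wv")]], Wo = pm[[paste0(p, "mhsa.Wo")]])
      if (cfg$extra_prenorm) {
        pre <- layernorm_fwd(X, pm[[paste0(p, "pre.g")]], pm[[paste0(p, "pre.b")]])
        at <- mhsa_fwd_b(pre$y, wts, cfg$heads, B)
        X <- X + (at$y - pre$y)       # residual around the normalized branch
        lc$pre <- pre$cache
      } else {
        at <- mhsa_fwd_b(X, wts, cfg$heads, B)
        X <- at$y
      }
      ml <- mlp_fwd(X, list(ln.g = pm[[paste0(p, "mlp.ln.g")]],
                            ln.b = pm[[paste0(p, "mlp.ln.b")]],
                            fc1.W = pm[[paste0(p, "mlp.fc1.W")]],
                            fc1.b = pm[[paste0(p, "mlp.fc1.b")]],
                            fc2.W = pm[[paste0(p, "mlp.fc2.W")]],
                            fc2.b = pm[[paste0(p, "mlp.fc2.b")]]))
      X <- ml$y
      lc$mhsa <- at$cache; lc$mlp <- ml$cache
      lay_caches[[l]] <- lc
    }
    Fsa <- aperm(array(X, c(g$N, B, hw)), c(3, 1, 2))   # (hw, N, B)
    Fsa <- array(Fsa, c(g$h, g$w, g$N, B))
    cs$ln0 <- ln0$cache; cs$layers <- lay_caches
    ops <- c(ops, list(Fsa))
  }
  # -- triplet path (three batched cross-dimension branches)
  if (cfg$triplet_attention) {
    tb <- vector("list", 3)
    for (j in 1:3) {
      perm <- triplet_perms[[j]]
      xp <- if (all(perm == 1:3)) Fw_arr else aperm(Fw_arr, c(perm, 4))
      key <- paste0("trip.", j)
      f <- trip_branch_fwd_b(xp, list(W = pm[[paste0(key, ".W")]],
                                      bn.g = pm[[paste0(key, ".bn.g")]],
                                      bn.b = pm[[paste0(key, ".bn.b")]]),
                             buffers, key, train)
      buffers[[paste0(key, ".rm")]] <- f$rm
      buffers[[paste0(key, ".rv")]] <- f$rv
      tb[[j]] <- f
    }
    Ftr <- (tb[[1]]$y + aperm(tb[[2]]$y, c(order(triplet_perms[[2]]), 4)) +
              aperm(tb[[3]]$y, c(order(triplet_perms[[3]]), 4))) / 3
    cs$trip <- lapply(tb, `[[`, "cache")
    ops <- c(ops, list(Ftr))
  }
  # -- global projection and fusion
  if (!g$degenerate) {
    x2g <- matrix(aperm(Fg_all, c(1, 2, 4, 3)), hw * B, g$c)
    gp <- sweep(x2g %*% pm$gproj.W, 2, pm$gproj.b, `+`)
    cs$x2g <- x2g
    Fgp <- aperm(array(gp, c(g$h, g$w, B, g$N)), c(1, 2, 4, 3))
    if ("gproj" %in% taps) cs$tap$gproj <- Fgp
    ops <- c(ops, list(Fgp))
    fused <- array(0, c(g$h, g$w, g$M, B))
    off <- 0
    for (o in ops) {
      fused[, , off + seq_len(dim(o)[3]), ] <- o
      off <- off + dim(o)[3]
    }
  } else {
    fused <- Fw_arr
  }
  if ("fusion" %in% taps) cs$tap$fusion <- fused
  # -- head: 1x1 conv, GAP, linear
  xf <- matrix(aperm(fused, c(1, 2, 4, 3)), hw * B, g$M)
  hc <- sweep(xf %*% pm$head.W, 2, pm$head.b, `+`)      # (hw*B) x N
  if ("head_conv" %in% taps)
    cs$tap$head_conv <- aperm(array(hc, c(g$h, g$w, B, g$N)), c(1, 2, 4, 3))
  gap <- matrix(colMeans(matrix(hc, hw, B * g$N)), B, g$N)
  logits <- sweep(gap %*% pm$fc.W, 2, pm$fc.b, `+`)
  cs$xf <- xf; cs$gap <- gap
  list(logits = logits,
       cache = list(stem = st$caches, cs = cs, kper = kper, P = P, B = B,
                    dims = dim(feat), geometry = g, train = train, taps = taps),
       buffers = buffers)
}

# Backward pass: dlogits is B x num_class. Returns named gradient list and,
# when taps were requested, batch gradient arrays at the tapped activations.
fbanet_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  g <- cache$geometry
  hw <- g$h * g$w
  pm <- model$params
  B <- cache$B
  kper <- cache$kper; P <- cache$P
  cs <- cache$cs
  gacc <- list()
  add_g <- function(acc, nm, val) {
    acc[[nm]] <- if (is.null(acc[[nm]])) val else acc[[nm]] + val
    acc
  }
  tap_grads <- list()
  # head
  gacc <- add_g(gacc, "fc.W", crossprod(cs$gap, dlogits))
  gacc <- add_g(gacc, "fc.b", colSums(dlogits))
  dgap <- dlogits %*% t(pm$fc.W)                        # B x N
  dhc <- dgap[rep(seq_len(B), each = hw), , drop = FALSE] / hw
  if ("head_conv" %in% cache$taps)
    tap_grads$head_conv <- aperm(array(dhc, c(g$h, g$w, B, g$N)), c(1, 2, 4, 3))
  gacc <- add_g(gacc, "head.W", crossprod(cs$xf, dhc))
  gacc <- add_g(gacc, "head.b", colSums(dhc))
  dxf <- dhc %*% t(pm$head.W)                           # (hw*B) x M
  dfused <- aperm(array(dxf, c(g$h, g$w, B, g$M)), c(1, 2, 4, 3))
  if ("fusion" %in% cache$taps) tap_grads$fusion <- dfused
  dFw_mat <- matrix(0, hw * B, g$N)                     # rows (pixel, sample)
  dFg_mat <- matrix(0, hw * B, g$c)
  off <- 0
  if (!g$degenerate) {
    if (cfg$self_attention) {
      dFsa <- array(dfused[, , off + seq_len(g$N), ], c(g$h, g$w, g$N, B))
      off <- off + g$N
      dX <- matrix(aperm(array(dFsa, c(hw, g$N, B)), c(2, 3, 1)), g$N * B, hw)
      for (l in rev(seq_len(cfg$layers))) {
        p <- paste0("attn.", l, ".")
        lc <- cs$layers[[l]]
        gm <- mlp_bwd(dX, lc$mlp)
        for (nm in names(gm$grads)) gacc <- add_g(gacc, paste0(p, "mlp.", nm), gm$grads[[nm]])
        dX <- gm$dx
        ga <- mhsa_bwd_b(dX, lc$mhsa)
        for (nm in names(ga$grads)) gacc <- add_g(gacc, paste0(p, "mhsa.", nm), ga$grads[[nm]])
        if (cfg$extra_prenorm) {
          dbranch <- ga$dx - dX               # gradient entering the pre-norm branch
          gp <- layernorm_bwd(dbranch, lc$pre)
          gacc <- add_g(gacc, paste0(p, "pre.g"), gp$dg)
          gacc <- add_g(gacc, paste0(p, "pre.b"), gp$db)
          dX <- dX + gp$dx
        } else {
          dX <- ga$dx
        }
      }
      g0 <- layernorm_bwd(dX, cs$ln0)
      gacc <- add_g(gacc, "ln0.g", g0$dg)
      gacc <- add_g(gacc, "ln0.b", g0$db)
      depos <- rowsum(g0$dx, rep(seq_len(g$N), B), reorder = TRUE)
      dimnames(depos) <- NULL
      gacc <- add_g(gacc, "epos", depos)
      # back to (pixel, sample) rows
      dFw_tok <- aperm(array(g0$dx, c(g$N, B, hw)), c(3, 2, 1))   # (hw, B, N)
      dFw_mat <- dFw_mat + matrix(dFw_tok, hw * B, g$N)
    }
    if (cfg$triplet_attention) {
      dFtr <- array(dfused[, , off + seq_len(g$N), ], c(g$h, g$w, g$N, B)) / 3
      off <- off + g$N
      dFw_tr <- array(0, c(g$h, g$w, g$N, B))
      for (j in 1:3) {
        perm <- triplet_perms[[j]]
        dyp <- if (all(perm == 1:3)) dFtr else aperm(dFtr, c(perm, 4))
        gb <- trip_branch_bwd_b(dyp, cs$trip[[j]])
        key <- paste0("trip.", j)
        gacc <- add_g(gacc, paste0(key, ".W"), gb$grads$W)
        gacc <- add_g(gacc, paste0(key, ".bn.g"), gb$grads$bn.g)
        gacc <- add_g(gacc, paste0(key, ".bn.b"), gb$grads$bn.b)
        dFw_tr <- dFw_tr + (if (all(perm == 1:3)) gb$dx else aperm(gb$dx, c(order(perm), 4)))
      }
      dFw_mat <- dFw_mat + matrix(aperm(dFw_tr, c(1, 2, 4, 3)), hw * B, g$N)
    }
    dgp <- matrix(aperm(array(dfused[, , off + seq_len(g$N), ], c(g$h, g$w, g$N, B)),
                        c(1, 2, 4, 3)), hw * B, g$N)
    if ("gproj" %in% cache$taps)
      tap_grads$gproj <- aperm(array(dgp, c(g$h, g$w, B, g$N)), c(1, 2, 4, 3))
    gacc <- add_g(gacc, "gproj.W", crossprod(cs$x2g, dgp))
    gacc <- add_g(gacc, "gproj.b", colSums(dgp))
    dFg_mat <- dFg_mat + dgp %*% t(pm$gproj.W)
  } else {
    dFw_mat <- dFw_mat + matrix(aperm(dfused, c(1, 2, 4, 3)), hw * B, g$N)
  }
  if ("fw" %in% cache$taps)
    tap_grads$fw <- aperm(array(dFw_mat, c(g$h, g$w, B, g$N)), c(1, 2, 4, 3))
  # channel adjustment
  gacc <- add_g(gacc, "adjust.W", crossprod(cs$x2, dFw_mat))
  gacc <- add_g(gacc, "adjust.b", colSums(dFw_mat))
  dFLG <- dFw_mat %*% t(pm$adjust.W)                    # (hw*B) x cin
  cin <- ncol(dFLG)
  dFLG_arr <- aperm(array(dFLG, c(g$h, g$w, B, cin)), c(1, 2, 4, 3))
  dfeat <- array(0, cache$dims)
  gidx <- seq_len(B) * kper
  if (P > 0) {
    dFhat <- array(dFLG_arr[, , seq_len(g$c), ], c(g$h, g$w, g$c, B)) / P
    for (i in seq_len(P)) dfeat[, , , (seq_len(B) - 1) * kper + i] <- dFhat
    dFg_arr <- array(dFLG_arr[, , g$c + seq_len(g$c), ], c(g$h, g$w, g$c, B))
  } else {
    dFg_arr <- dFLG_arr
  }
  dFg_arr <- dFg_arr + aperm(array(dFg_mat, c(g$h, g$w, B, g$c)), c(1, 2, 4, 3))
  if ("stem_global" %in% cache$taps) tap_grads$stem_global <- dFg_arr
  dfeat[, , , gidx] <- dFg_arr
  spec <- stem_spec(cfg$stem)
  sb <- seq_bwd(spec$layers, "stem", pm, cache$stem, dfeat, need_input_grad = FALSE)
  for (nm in names(sb$grads)) gacc <- add_g(gacc, nm, sb$grads[[nm]])
  list(grads = gacc, tap_grads = tap_grads)
}

# Loss + gradients for a labeled batch of normalized images.
fbanet_grad <- function(model, xg, labels, train = TRUE) {
  fwd <- fbanet_forward(model, xg, train = train)
  ce <- cross_entropy_logits(fwd$logits, labels)
  bwd <- fbanet_backward(model, fwd$cache, ce$dlogits)
  list(loss = ce$loss, logits = fwd$logits, grads = bwd$grads, buffers = fwd$buffers)
}

# Preprocess a sketch_image (or raw array) into a normalized (s, s, 3) array.
preprocess_image <- function(image, config) {
  px <- if (inherits(image, "sketch_image")) image$pixels else image
  if (inherits(image, "sketch_image") && image$background == "black")
    px <- 255 - px
  if (any(dim(px)[1:2] != config$input_side))
    px <- resize_bilinear(px, config$input_side, config$input_side)
  normalize_pixels(clamp(px, 0, 255), config$norm_mean, config$norm_sd)
}

#' Predict from a bi-level attention network
#'
#' @param object an [fbanet()] model.
#' @param images a [sketch_image()], a list of them, or a `sketch_dataset`.
#' @param type `"prob"` (softmax probabilities), `"class"` (argmax class ids,
#'   0-based) or `"logit"`.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return Matrix of probabilities/logits, or an integer vector of class ids.
#' @export
predict.fbanet <- function(object, images, type = c("prob", "class", "logit"),
                           batch_size = 16, ...) {
  type <- match.arg(type)
  if (inherits(images, "sketch_dataset")) images <- images$images
  if (inherits(images, "sketch_image") || (is.array(images) && length(dim(images)) == 3))
    images <- list(images)
  cfg <- object$config
  n <- length(images)
  out <- matrix(0, n, cfg$num_class)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    xg <- array(0, c(cfg$input_side, cfg$input_side, 3, length(idx)))
    for (j in seq_along(idx)) xg[, , , j] <- preprocess_image(images[[idx[j]]], cfg)
    out[idx, ] <- fbanet_forward(object, xg, train = FALSE)$logits
  }
  switch(type,
    logit = out,
    prob = softmax_rows(out),
    class = max.col(out, ties.method = "first") - 1L)
}

# ---- standalone spec operations -------------------------------------------

#' Average local patch features
#'
#' Elementwise arithmetic mean of the P patch feature tensors (shape
#' preserved); the first half of the feature-enhancement fusion.
#'
#' @param features non-empty list of equally shaped arrays.
#' @return Array of the same shape, the elementwise mean.
#' @export
average_local_features <- function(features) {
  if (!is.list(features) || length(features) == 0) stopf("non-empty list of tensors required")
  d <- dim(features[[1]])
  for (f in features) if (!identical(dim(f), d)) stopf("all feature tensors must share a shape")
  Reduce(`+`, features) / length(features)
}

#' Feature enhancement: fuse local and global stem features
#'
#' Concatenates the averaged local features with the global features along
#' channels and adjusts the channel count with a learned 1x1 convolution.
#' With `enhance = FALSE` (ablation) the local branch is bypassed and the
#' global features alone are mapped through the 1x1 convolution.
#'
#' @param local_avg,global_feat `(h, w, c)` arrays of identical shape.
#' @param adjusted_channels output channel count N.
#' @param weights optional list with `W` (`cin x N`) and `b` (length N).
#' @param enhance include the local branch (default TRUE).
#' @param seed seed for default weights.
#' @return `(h, w, N)` array.
#' @export
feature_enhance <- function(local_avg, global_feat, adjusted_channels = 256,
                            weights = NULL, enhance = TRUE, seed = 0) {
  d <- dim(global_feat)
  if (enhance && !identical(dim(local_avg), d)) stopf("local and global feature shapes differ")
  x <- if (enhance) array(c(local_avg, global_feat), c(d[1], d[2], 2 * d[3])) else global_feat
  cin <- dim(x)[3]
  if (is.null(weights)) weights <- with_seed(seed, list(
    W = matrix(stats::rnorm(cin * adjusted_channels, sd = sqrt(2 / cin)), cin, adjusted_channels),
    b = numeric(adjusted_channels)))
  y <- sweep(matrix(x, d[1] * d[2], cin) %*% weights$W, 2, weights$b, `+`)
  array(y, c(d[1], d[2], ncol(weights$W)))
}

#' Bi-level fusion with global-feature compensation
#'
#' Channel-wise concatenation of the reshaped self-attention output, the
#' triplet-attention output, and a 1x1-convolution projection of the global
#' stem features. Either attention operand may be dropped (ablation) while
#' the result stays consumable by the head.
#'
#' @param self_attn_out `N x d` token matrix (with `hw` attribute, as produced
#'   by [embed_sequence()]) or `(h, w, N)` array; `NULL` to drop.
#' @param triplet_out `(h, w, N)` array; `NULL` to drop.
#' @param global_feat `(h, w, c)` global stem features.
#' @param weights optional list with `W` (`c x N`), `b` (length N) for the
#'   global projection.
#' @param adjusted_channels N used for default projection weights.
#' @param seed seed for default weights.
#' @return `(h, w, M)` fused array.
#' @export
bi_level_fuse <- function(self_attn_out, triplet_out, global_feat, weights = NULL,
                          adjusted_channels = NULL, seed = 0) {
  d <- dim(global_feat)
  ops <- list()
  if (!is.null(self_attn_out)) {
    if (is.matrix(self_attn_out)) {
      hw <- attr(self_attn_out, "hw") %||% d[1:2]
      self_attn_out <- array(t(self_attn_out), c(hw[1], hw[2], nrow(self_attn_out)))
    }
    ops <- c(ops, list(self_attn_out))
  }
  if (!is.null(triplet_out)) ops <- c(ops, list(triplet_out))
  if (length(ops) == 0) stopf("at least one attention operand is required")
  for (o in ops) if (!all(dim(o)[1:2] == d[1:2])) stopf("spatial dimensions disagree")
  N <- adjusted_channels %||% dim(ops[[1]])[3]
  if (is.null(weights)) weights <- with_seed(seed, list(
    W = matrix(stats::rnorm(d[3] * N, sd = sqrt(2 / d[3])), d[3], N), b = numeric(N)))
  gp <- sweep(matrix(global_feat, d[1] * d[2], d[3]) %*% weights$W, 2, weights$b, `+`)
  ops <- c(ops, list(array(gp, c(d[1], d[2], ncol(weights$W)))))
  ch <- sum(vapply(ops, function(o) dim(o)[3], numeric(1)))
  array(unlist(ops, use.names = FALSE), c(d[1], d[2], ch))
}

#' Classification head
#'
#' 1x1 convolution for channel reduction, global average pooling over the
#' spatial plane, and a fully connected layer producing one logit per class.
#'
#' @param f `(h, w, M)` fused feature array.
#' @param num_class number of classes.
#' @param weights optional list with `conv.W` (`M x N`), `conv.b`, `fc.W`
#'   (`N x num_class`), `fc.b`.
#' @param reduced_channels N for default weights (default `M`).
#' @param seed seed for default weights.
#' @return Numeric vector of `num_class` logits.
#' @export
classification_head <- function(f, num_class, weights = NULL,
                                reduced_channels = NULL, seed = 0) {
  d <- dim(f)
  M <- d[3]
  N <- reduced_channels %||% M
  if (is.null(weights)) weights <- with_seed(seed, list(
    conv.W = matrix(stats::rnorm(M * N, sd = sqrt(2 / M)), M, N), conv.b = numeric(N),
    fc.W = matrix(stats::rnorm(N * num_class, sd = 0.01), N, num_class),
    fc.b = numeric(num_class)))
  hc <- sweep(matrix(f, d[1] * d[2], M) %*% weights$conv.W, 2, weights$conv.b, `+`)
  gap <- colMeans(hc)
  as.vector(gap %*% weights$fc.W) + weights$fc.b
}

# ---- checkpoints ----------------------------------------------------------

#' Save or load a model checkpoint
#'
#' A checkpoint is a flat named-parameter archive with the configuration and
#' normalization buffers embedded; round-trips are bit-exact.
#'
#' @param model an [fbanet()] model.
#' @param path file path (`.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `fbanet` model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "fbanet"))
  saveRDS(list(config = model$config, params = model$params, buffers = model$buffers,
               format = "fbanet-checkpoint-1"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "fbanet-checkpoint-1")) stopf("not an fbanet checkpoint: %s", path)
  structure(list(config = ck$config, params = ck$params, buffers = ck$buffers),
            class = "fbanet")
}

#' Adapt a pretrained model to a new class count
#'
#' Replaces only the final fully connected layer (e.g. 345 pre-training
#' classes to the binary screening task); every other weight, including the
#' positional encoding, is retained.
#'
#' @param model a pretrained [fbanet()] model.
#' @param num_class new class count.
#' @param seed seed for the fresh head weights.
#' @return The adapted `fbanet` model.
#' @export
transfer_head <- function(model, num_class, seed = 0) {
  stopifnot(inherits(model, "fbanet"))
  cfg <- model$config
  cfg$num_class <- as.integer(num_class)
  N <- nrow(model$params$fc.W)
  model$params$fc.W <- with_seed(seed, matrix(stats::rnorm(N * num_class, sd = 0.01), N, num_class))
  model$params$fc.b <- numeric(num_class)
  model$config <- cfg
  model
}
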