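# Neural-network primitives in base R matrix algebra. Every *_fwd returns a
# list with the output and a cache; the matching *_bwd consumes the cache and
# the upstream gradient. Feature maps are stored (h, w, c) per image and
# (h, w, c, n) for batches; convolution weights are (k*k*cin) x cout matrices
# with kernel-row fastest, then kernel-col, then input channel (the im2col
# column order below).

# ---- im2col ---------------------------------------------------------------

# Index map for one (h, w, c) image: matrix (ho*wo) x (k*k*c) of linear
# indices into the zero-padded (hp, wp, c) array. Cached per geometry.
im2col_idx <- function(h, w, c, k, stride, pad) {
  key <- paste("i2c", h, w, c, k, stride, pad, sep = "_")
  ii <- .fba_env[[key]]
  if (!is.null(ii)) return(ii)
  hp <- h + 2 * pad; wp <- w + 2 * pad
  ho <- (hp - k) %/% stride + 1
  wo <- (wp - k) %/% stride + 1
  oi <- (seq_len(ho) - 1) * stride          # top row of each window (0-based)
  oj <- (seq_len(wo) - 1) * stride
  # base offsets within a window: a (row, fastest), b (col), ci (channel)
  a <- rep(seq_len(k), times = k * c)
  b <- rep(rep(seq_len(k), each = k), times = c)
  ci <- rep(seq_len(c), each = k * k)
  win <- a + hp * (b - 1) + hp * wp * (ci - 1)          # length k*k*c
  pos <- rep(oi, times = wo) + hp * rep(oj, each = ho)  # length ho*wo
  idx <- outer(as.integer(pos), as.integer(win), `+`)    # (ho*wo) x (k*k*c)
  storage.mode(idx) <- "integer" 
  ii <- list(idx = idx, ho = ho, wo = wo, hp = hp, wp = wp)
  .fba_env[[key]] <- ii
  ii
}

pad_batch <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

# ---- convolution ----------------------------------------------------------

# Batch im2col index: rows ordered (output position fastest, then image),
# columns (kernel row, kernel col, channel). Cached per geometry x batch size.
im2col_idx_batch <- function(h, w, c, k, stride, pad, n) {
  key <- paste("i2cb", h, w, c, k, stride, pad, n, sep = "_")
  bb <- .fba_env[[key]]
  if (!is.null(bb)) return(bb)
  ii <- im2col_idx(h, w, c, k, stride, pad)
  L <- nrow(ii$idx)
  sz <- ii$hp * ii$wp * c
  big <- ii$idx[rep(seq_len(L), n), , drop = FALSE] +
    rep(as.integer((seq_len(n) - 1) * sz), each = L)
  storage.mode(big) <- "integer" 
  bb <- list(big = big, ho = ii$ho, wo = ii$wo, hp = ii$hp, wp = ii$wp, L = L)
  .fba_env[[key]] <- bb
  bb
}

conv2d_fwd <- function(x, W, b = NULL, stride = 1, pad = 0) {
  d <- dim(x)  # (h, w, cin, n)
  n <- d[4]; cin <- d[3]
  cout <- ncol(W)
  k <- as.integer(round(sqrt(nrow(W) / cin)))
  xp <- pad_batch(x, pad)
  ii <- im2col_idx_batch(d[1], d[2], cin, k, stride, pad, n)
  L <- ii$L; ckk <- nrow(W)
  cols <- matrix(xp[ii$big], L * n, ckk)
  y <- cols %*% W
  if (!is.null(b)) y <- y + rep(b, each = L * n)
  dim(y) <- c(L, n, cout)
  y <- aperm(y, c(1, 3, 2))
  dim(y) <- c(ii$ho, ii$wo, cout, n)
  list(y = y, cache = list(cols = cols, W = W, has_b = !is.null(b), dims = d,
                           k = k, stride = stride, pad = pad, ii = ii))
}

conv2d_bwd <- function(dy, cache, need_dx = TRUE) {
  d <- cache$dims; ii <- cache$ii
  n <- d[4]; cin <- d[3]
  L <- ii$L
  cout <- ncol(cache$W); ckk <- nrow(cache$W)
  dim(dy) <- c(L, cout, n)
  dy <- aperm(dy, c(1, 3, 2))
  dim(dy) <- c(L * n, cout)
  dW <- crossprod(cache$cols, dy)
  db <- if (cache$has_b) colSums(dy) else NULL
  if (!need_dx) return(list(dx = NULL, dW = dW, db = db))
  dcols <- dy %*% t(cache$W)         # (L*n) x ckk
  dxp <- numeric(ii$hp * ii$wp * cin * n)
  big <- cache$ii$big
  for (j in seq_len(ckk)) {
    tgt <- big[, j]                  # distinct within a column
    dxp[tgt] <- dxp[tgt] + dcols[, j]
  }
  dim(dxp) <- c(ii$hp, ii$wp, cin, n)
  p <- cache$pad
  dx <- if (p > 0) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = db)
}

# ---- pooling --------------------------------------------------------------

maxpool_fwd <- function(x, k = 3, stride = 2, pad = 1) {
  d <- dim(x)  # (h, w, c, n)
  cn <- d[3] * d[4]
  ii <- im2col_idx(d[1], d[2], 1L, k, stride, pad)
  xp <- pad_batch(x, pad)
  # padded positions outside the image should never win the max
  if (pad > 0) {
    mask <- array(-Inf, c(ii$hp, ii$wp)); mask[pad + seq_len(d[1]), pad + seq_len(d[2])] <- 0
    xp <- xp + array(mask, dim(xp))
  }
  xmat <- matrix(xp, ncol = cn)
  cols <- xmat[as.vector(ii$idx), , drop = FALSE]
  L <- ii$ho * ii$wo
  dim(cols) <- c(L, k * k, cn)
  am <- apply(cols, c(1, 3), which.max)
  y <- apply(cols, c(1, 3), max)
  dim(y) <- c(ii$ho, ii$wo, d[3], d[4])
  list(y = y, cache = list(am = am, ii = ii, dims = d, k = k, pad = pad, cn = cn))
}

maxpool_bwd <- function(dy, cache) {
  d <- cache$dims; ii <- cache$ii; cn <- cache$cn
  L <- ii$ho * ii$wo
  dxp <- matrix(0, ii$hp * ii$wp, cn)
  dym <- matrix(dy, nrow = L)
  win_off <- ii$idx  # (L x k*k)
  for (col in seq_len(cn)) {
    # scatter-add: winning positions can repeat across overlapping windows
    tgt <- win_off[cbind(seq_len(L), cache$am[, col])]
    acc <- rowsum(dym[, col], tgt)
    dxp[as.integer(rownames(acc)), col] <- dxp[as.integer(rownames(acc)), col] + acc[, 1]
  }
  dim(dxp) <- c(ii$hp, ii$wp, d[3], d[4])
  p <- cache$pad
  if (p > 0) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE] else dxp
}

# ---- activations ----------------------------------------------------------

relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dy, cache) dy * cache

gelu_fwd <- function(x) {
  ph <- stats::pnorm(x)
  list(y = x * ph, cache = list(x = x, ph = ph))
}
gelu_bwd <- function(dy, cache) dy * (cache$ph + cache$x * stats::dnorm(cache$x))

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

# ---- layer norm (per row of an N x d matrix) ------------------------------

layernorm_fwd <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2, g, `*`)
  y <- sweep(y, 2, b, `+`)
  list(y = y, cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, cache$g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# ---- normalization over spatial extent (instance-style batch norm) --------
# x: (h, w, c, n); statistics per (channel, sample) over the spatial plane
# during training, running moments at eval. g, b: per channel.

bnorm_fwd <- function(x, g, b, rm, rv, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  hw <- d[1] * d[2]
  xm <- matrix(x, nrow = hw)                 # hw x (c*n)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    mu_c <- rowMeans(matrix(mu, d[3], d[4]))
    v_c <- rowMeans(matrix(v, d[3], d[4]))
    rm_new <- (1 - momentum) * rm + momentum * mu_c
    rv_new <- (1 - momentum) * rv + momentum * v_c
  } else {
    mu <- rep(rep(rm, d[4]), 1)
    v <- rep(rep(rv, d[4]), 1)
    rm_new <- rm; rv_new <- rv
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu, `-`), 2, inv, `*`)
  gc <- rep(g, d[4]); bc <- rep(b, d[4])
  y <- sweep(sweep(xhat, 2, gc, `*`), 2, bc, `+`)
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, inv = inv, g = gc, dims = d, train = train),
       rm = rm_new, rv = rv_new)
}

bnorm_bwd <- function(dy, cache) {
  d <- cache$dims
  hw <- d[1] * d[2]
  dym <- matrix(dy, nrow = hw)
  xhat <- cache$xhat
  dg_cn <- colSums(dym * xhat)
  db_cn <- colSums(dym)
  dxhat <- sweep(dym, 2, cache$g, `*`)
  if (cache$train) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- sweep(dxhat, 2, m1, `-`) - sweep(xhat, 2, m2, `*`)
    dx <- sweep(dx, 2, cache$inv, `*`)
  } else {
    dx <- sweep(dxhat, 2, cache$inv, `*`)
  }
  dim(dx) <- d
  list(dx = dx,
       dg = rowSums(matrix(dg_cn, d[3], d[4])),
       db = rowSums(matrix(db_cn, d[3], d[4])))
}

# ---- linear ---------------------------------------------------------------

linear_fwd <- function(x, W, b = NULL) {
  y <- x %*% W
  if (!is.null(b)) y <- sweep(y, 2, b, `+`)
  list(y = y, cache = list(x = x, W = W, has_b = !is.null(b)))
}

linear_bwd <- function(dy, cache) {
  list(dx = dy %*% t(cache$W),
       dW = crossprod(cache$x, dy),
       db = if (cache$has_b) colSums(dy) else NULL)
}
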