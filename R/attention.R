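# Token-sequence self-attention path: embedding with learnable positional
# encoding, multi-head self-attention, and the transformer MLP, each with a
# hand-written backward pass. Tokens are the N channels of the enhanced
# feature map; the embedding width is d = h*w (no class token).

# Effective head count: the largest divisor of d not exceeding the requested
# number. The classic full-scale geometry gives d = 49 spatial positions,
# which no power of two divides, so a configured n = 8 falls back to 7.
effective_heads <- function(d, heads) {
  h <- min(heads, d)
  while (d %% h != 0) h <- h - 1
  h
}

#' Flatten a feature tensor into a token sequence
#'
#' Each of the N channels of an `(h, w, N)` feature block becomes one token of
#' width `d = h*w`; a learnable positional encoding is added and the rows are
#' layer-normalized. No class token is used.
#'
#' @param fw `(h, w, N)` feature array.
#' @param epos optional `N x d` positional encoding (default all zero).
#' @param gamma,beta optional layer-norm scale/shift of length `d` (defaults
#'   1 and 0).
#' @return `N x d` matrix of embedded tokens (attribute `hw` records the
#'   spatial shape).
#' @export
embed_sequence <- function(fw, epos = NULL, gamma = NULL, beta = NULL) {
  d3 <- dim(fw)
  stopifnot(length(d3) == 3)
  d <- d3[1] * d3[2]
  X <- t(matrix(fw, d, d3[3]))
  if (!is.null(epos)) X <- X + epos
  f <- layernorm_fwd(X, gamma %||% rep(1, d), beta %||% numeric(d))
  structure(f$y, hw = d3[1:2])
}

mhsa_init <- function(d, seed = 0) {
  with_seed(seed, list(
    Wq = matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d),
    Wk = matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d),
    Wv = matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d),
    Wo = matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d)
  ))
}

mhsa_fwd <- function(X, weights, heads) {
  d <- ncol(X); N <- nrow(X)
  nh <- effective_heads(d, heads)
  dh <- d %/% nh
  Q <- X %*% weights$Wq; K <- X %*% weights$Wk; V <- X %*% weights$Wv
  O <- matrix(0, N, d)
  A_list <- vector("list", nh)
  for (h in seq_len(nh)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) / sqrt(dh)
    A <- softmax_rows(S)
    A_list[[h]] <- A
    O[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  proj <- O %*% weights$Wo
  list(y = X + proj,
       cache = list(X = X, Q = Q, K = K, V = V, O = O, A = A_list,
                    nh = nh, dh = dh, weights = weights))
}

mhsa_bwd <- function(dy, cache) {
  w <- cache$weights
  X <- cache$X
  dproj <- dy                      # residual: dX gets dy directly too
  dO <- dproj %*% t(w$Wo)
  dWo <- crossprod(cache$O, dproj)
  dQ <- matrix(0, nrow(X), ncol(X)); dK <- dQ; dV <- dQ
  for (h in seq_len(cache$nh)) {
    idx <- ((h - 1) * cache$dh + 1):(h * cache$dh)
    A <- cache$A[[h]]
    Vh <- cache$V[, idx, drop = FALSE]
    dOh <- dO[, idx, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, idx] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))          # softmax backward, row-wise
    dS <- dS / sqrt(cache$dh)
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE]
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE])
  }
  dX <- dy + dQ %*% t(w$Wq) + dK %*% t(w$Wk) + dV %*% t(w$Wv)
  list(dx = dX,
       grads = list(Wq = crossprod(X, dQ), Wk = crossprod(X, dK),
                    Wv = crossprod(X, dV), Wo = dWo))
}

#' Multi-head self-attention with residual connection
#'
#' Scaled dot-product attention per head (scale `1/sqrt(d/heads)`), heads
#' concatenated, projected, and added residually to the input sequence.
#'
#' @param seq `N x d` token matrix.
#' @param heads requested head count; must divide `d` (a configured count that
#'   does not divide `d` is reduced to the largest divisor below it inside the
#'   assembled model, but this standalone op is strict).
#' @param weights list with `Wq`, `Wk`, `Wv`, `Wo` (`d x d` each); randomly
#'   initialized from `seed` when omitted.
#' @param seed seed for default weights.
#' @param return_attention also return the per-head row-stochastic attention
#'   matrices.
#' @return `N x d` output sequence; with `return_attention = TRUE`, a list
#'   `(tokens, attention)`.
#' @export
multi_head_self_attention <- function(seq, heads = 8, weights = NULL, seed = 0,
                                      return_attention = FALSE) {
  d <- ncol(seq)
  if (d %% heads != 0) stopf("token width %d is not divisible by %d heads", d, heads)
  if (is.null(weights)) weights <- mhsa_init(d, seed)
  f <- mhsa_fwd(seq, weights, heads)
  if (return_attention) list(tokens = f$y, attention = f$cache$A) else f$y
}

mlp_init <- function(d, ratio = 4, seed = 0) {
  dh <- d * ratio
  with_seed(seed, list(
    ln.g = rep(1, d), ln.b = numeric(d),
    fc1.W = matrix(stats::rnorm(d * dh, sd = sqrt(2 / d)), d, dh), fc1.b = numeric(dh),
    fc2.W = matrix(stats::rnorm(dh * d, sd = sqrt(1 / dh)), dh, d), fc2.b = numeric(d)
  ))
}

# Batched MHSA over B stacked token blocks: X is (B*N) x d with sample b in
# rows (b-1)*N + 1:N. Projections are shared single matmuls; only the
# attention scores are computed per (sample, head) block.
mhsa_fwd_b <- function(X, weights, heads, B) {
  d <- ncol(X); Nt <- nrow(X) %/% B
  nh <- effective_heads(d, heads)
  dh <- d %/% nh
  Q <- X %*% weights$Wq; K <- X %*% weights$Wk; V <- X %*% weights$Wv
  O <- matrix(0, nrow(X), d)
  A_all <- vector("list", B * nh)
  for (b in seq_len(B)) {
    rows <- (b - 1) * Nt + seq_len(Nt)
    for (h in seq_len(nh)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      S <- (Q[rows, idx, drop = FALSE] %*% t(K[rows, idx, drop = FALSE])) / sqrt(dh)
      A <- softmax_rows(S)
      A_all[[(b - 1) * nh + h]] <- A
      O[rows, idx] <- A %*% V[rows, idx, drop = FALSE]
    }
  }
  proj <- O %*% weights$Wo
  list(y = X + proj,
       cache = list(X = X, Q = Q, K = K, V = V, O = O, A = A_all,
                    nh = nh, dh = dh, B = B, Nt = Nt, weights = weights))
}

mhsa_bwd_b <- function(dy, cache) {
  w <- cache$weights
  X <- cache$X
  dO <- dy %*% t(w$Wo)
  dWo <- crossprod(cache$O, dy)
  dQ <- matrix(0, nrow(X), ncol(X)); dK <- dQ; dV <- dQ
  for (b in seq_len(cache$B)) {
    rows <- (b - 1) * cache$Nt + seq_len(cache$Nt)
    for (h in seq_len(cache$nh)) {
      idx <- ((h - 1) * cache$dh + 1):(h * cache$dh)
      A <- cache$A[[(b - 1) * cache$nh + h]]
      Vh <- cache$V[rows, idx, drop = FALSE]
      dOh <- dO[rows, idx, drop = FALSE]
      dA <- dOh %*% t(Vh)
      dV[rows, idx] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dS <- dS / sqrt(cache$dh)
      dQ[rows, idx] <- dS %*% cache$K[rows, idx, drop = FALSE]
      dK[rows, idx] <- crossprod(dS, cache$Q[rows, idx, drop = FALSE])
    }
  }
  dX <- dy + dQ %*% t(w$Wq) + dK %*% t(w$Wk) + dV %*% t(w$Wv)
  list(dx = dX,
       grads = list(Wq = crossprod(X, dQ), Wk = crossprod(X, dK),
                    Wv = crossprod(X, dV), Wo = dWo))
}

mlp_fwd <- function(X, w) {
  ln <- layernorm_fwd(X, w$ln.g, w$ln.b)
  f1 <- linear_fwd(ln$y, w$fc1.W, w$fc1.b)
  g <- gelu_fwd(f1$y)
  f2 <- linear_fwd(g$y, w$fc2.W, w$fc2.b)
  list(y = X + f2$y, cache = list(ln = ln$cache, f1 = f1$cache, g = g$cache, f2 = f2$cache))
}

mlp_bwd <- function(dy, cache) {
  g2 <- linear_bwd(dy, cache$f2)
  dg <- gelu_bwd(g2$dx, cache$g)
  g1 <- linear_bwd(dg, cache$f1)
  gl <- layernorm_bwd(g1$dx, cache$ln)
  list(dx = dy + gl$dx,
       grads = list(ln.g = gl$dg, ln.b = gl$db, fc1.W = g1$dW, fc1.b = g1$db,
                    fc2.W = g2$dW, fc2.b = g2$db))
}

#' Transformer MLP sub-block with pre-norm residual
#'
#' LayerNorm, a two-layer fully connected network with GELU nonlinearity
#' (expansion ratio 4 by default), and a residual connection. Inside the
#' assembled model this alternates with [multi_head_self_attention()] for L
#' layers.
#'
#' @param seq `N x d` token matrix.
#' @param weights list with `ln.g`, `ln.b`, `fc1.W`, `fc1.b`, `fc2.W`,
#'   `fc2.b`; randomly initialized from `seed` when omitted.
#' @param ratio hidden-width expansion ratio for default weights.
#' @param seed seed for default weights.
#' @return `N x d` output sequence.
#' @export
transformer_mlp <- function(seq, weights = NULL, ratio = 4, seed = 0) {
  if (is.null(weights)) weights <- mlp_init(ncol(seq), ratio, seed)
  mlp_fwd(seq, weights)$y
}
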