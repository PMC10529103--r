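# Triplet attention: three cross-dimension gating branches. Each branch
# optionally permutes the (h, w, N) feature block so a different pair of
# dimensions forms the convolution plane, summarizes the remaining dimension
# with Zpool (max + mean), passes the 2-channel summary through a 7x7
# same-padded convolution, batch norm, and a sigmoid gate, multiplies the
# gate back into the (permuted) input, and permutes back. The three branch
# outputs are averaged.
#
# Internally feature blocks are (h, w, N); the branch permutations are
#   none      : plane (h, w), pool over N          (identity permutation)
#   swap_w_N  : plane (N, w), pool over h          (aperm 3,2,1)
#   swap_h_N  : plane (h, N), pool over w          (aperm 1,3,2)

triplet_perms <- list(none = c(1, 2, 3), swap_w_N = c(3, 2, 1), swap_h_N = c(1, 3, 2))

#' Z-pool: max and mean over the leading dimension
#'
#' Compresses an `N x h x w` feature block to a 2-channel spatial summary by
#' concatenating the elementwise maximum and mean taken across the leading
#' (channel) dimension.
#'
#' @param t a 3-d array. Following the package's internal layout the pooled
#'   dimension is the third (`(h, w, N)` in, `(h, w, 2)` out); an array tagged
#'   with `channels_first = TRUE` attribute is interpreted as `(N, h, w)`.
#' @return 3-d array with two channels: max, then mean.
#' @export
z_pool <- function(t) {
  stopifnot(is.array(t), length(dim(t)) == 3)
  cf <- isTRUE(attr(t, "channels_first"))
  if (cf) t <- aperm(t, c(2, 3, 1))
  d <- dim(t)
  m <- matrix(t, d[1] * d[2], d[3])
  out <- array(c(apply(m, 1, max), rowMeans(m)), c(d[1], d[2], 2))
  if (cf) out <- aperm(out, c(3, 1, 2))
  out
}

zpool_fwd <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  am <- max.col(m, ties.method = "first")
  y <- array(c(m[cbind(seq_len(nrow(m)), am)], rowMeans(m)), c(d[1], d[2], 2))
  list(y = y, cache = list(am = am, dims = d))
}

zpool_bwd <- function(dy, cache) {
  d <- cache$dims
  hw <- d[1] * d[2]
  dmx <- matrix(dy[, , 1], hw)
  dmn <- matrix(dy[, , 2], hw)
  dm <- matrix(rep(dmn / d[3], d[3]), hw, d[3])
  dm[cbind(seq_len(hw), cache$am)] <- dm[cbind(seq_len(hw), cache$am)] + dmx
  array(dm, d)
}

# Batched Zpool over (a, b, C, B) arrays: pool over dim 3 per sample.
zpool_fwd_b <- function(x) {
  d <- dim(x)
  ab <- d[1] * d[2]
  Xm <- matrix(aperm(x, c(1, 2, 4, 3)), ab * d[4], d[3])
  am <- max.col(Xm, ties.method = "first")
  mx <- Xm[cbind(seq_len(nrow(Xm)), am)]
  mn <- rowMeans(Xm)
  tmp <- array(c(mx, mn), c(ab, d[4], 2))
  y <- array(aperm(tmp, c(1, 3, 2)), c(d[1], d[2], 2, d[4]))
  list(y = y, cache = list(am = am, dims = d))
}

zpool_bwd_b <- function(dy, cache) {
  d <- cache$dims
  ab <- d[1] * d[2]
  tmp <- array(aperm(dy, c(1, 2, 4, 3)), c(ab * d[4], 2))
  dXm <- matrix(rep(tmp[, 2] / d[3], d[3]), ab * d[4], d[3])
  dXm[cbind(seq_len(nrow(dXm)), cache$am)] <-
    dXm[cbind(seq_len(nrow(dXm)), cache$am)] + tmp[, 1]
  aperm(array(dXm, c(ab, d[4], d[3])), c(1, 3, 2)) |>
    array(dim = c(d[1], d[2], d[3], d[4]))
}

# Batched cross-dimension branch on already permuted (a, b, C, B) input.
trip_branch_fwd_b <- function(xp, w, buffers, key, train) {
  d <- dim(xp)
  zp <- zpool_fwd_b(xp)
  cv <- conv2d_fwd(zp$y, w$W, NULL, stride = 1, pad = 3)
  bn <- bnorm_fwd(cv$y, w$bn.g, w$bn.b, buffers[[paste0(key, ".rm")]],
                  buffers[[paste0(key, ".rv")]], train)
  gate <- array(sigmoid(bn$y[, , 1, ]), c(d[1], d[2], d[4]))   # (a, b, B)
  gate_e <- aperm(array(gate, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  y <- xp * gate_e
  list(y = y, cache = list(zp = zp$cache, cv = cv$cache, bn = bn$cache,
                           xp = xp, gate = gate, gate_e = gate_e, dims = d),
       rm = bn$rm, rv = bn$rv)
}

trip_branch_bwd_b <- function(dy, cache) {
  d <- cache$dims
  ab <- d[1] * d[2]
  m <- matrix(aperm(dy * cache$xp, c(1, 2, 4, 3)), ab * d[4], d[3])
  dgate <- rowSums(m)                                   # (a*b*B)
  g <- as.vector(cache$gate)                            # matches dgate order? see below
  # gate order: (a, b, B); m rows ordered (a, b, B) as well
  dpre <- dgate * g * (1 - g)
  dxp <- dy * cache$gate_e
  bn <- bnorm_bwd(array(dpre, c(d[1], d[2], 1, d[4])), cache$bn)
  cv <- conv2d_bwd(bn$dx, cache$cv)
  dz <- zpool_bwd_b(cv$dx, cache$zp)
  list(dx = dxp + dz, grads = list(W = cv$dW, bn.g = bn$dg, bn.b = bn$db))
}

trip_branch_init <- function(seed = 0) {
  with_seed(seed, list(
    W = matrix(stats::rnorm(98, sd = sqrt(2 / 98)), 98, 1),
    bn.g = 1, bn.b = 0
  ))
}

# forward of one branch on an already permuted (a, b, c) block; returns gate
# cache for backward.
trip_branch_fwd <- function(xp, w, buffers, key, train) {
  zp <- zpool_fwd(xp)
  d2 <- dim(zp$y)
  cv <- conv2d_fwd(array(zp$y, c(d2, 1)), w$W, NULL, stride = 1, pad = 3)
  bn <- bnorm_fwd(cv$y, w$bn.g, w$bn.b, buffers[[paste0(key, ".rm")]],
                  buffers[[paste0(key, ".rv")]], train)
  gate <- sigmoid(bn$y[, , 1, 1])
  y <- xp * as.vector(gate)             # broadcast over third dim
  list(y = y, gate = gate,
       cache = list(zp = zp$cache, cv = cv$cache, bn = bn$cache, xp = xp, gate = gate),
       rm = bn$rm, rv = bn$rv)
}

trip_branch_bwd <- function(dy, cache) {
  xp <- cache$xp; gate <- cache$gate
  d <- dim(xp)
  dgate <- rowSums(matrix(dy * xp, d[1] * d[2], d[3]))
  dxp <- dy * as.vector(gate)
  dpre <- dgate * as.vector(gate) * (1 - as.vector(gate))
  bn <- bnorm_bwd(array(dpre, c(d[1], d[2], 1, 1)), cache$bn)
  cv <- conv2d_bwd(bn$dx, cache$cv)
  dz <- zpool_bwd(cv$dx[, , , 1, drop = TRUE], cache$zp)
  list(dx = dxp + dz, grads = list(W = cv$dW, bn.g = bn$dg, bn.b = bn$db))
}

#' One cross-dimension attention branch
#'
#' Permutes the feature block (optionally), applies Zpool, a 7x7 same-padded
#' convolution (2 channels to 1), batch normalization and a sigmoid gate,
#' multiplies the gate into the permuted input elementwise, and permutes
#' back. Output shape equals input shape.
#'
#' @param t `(h, w, N)` feature array.
#' @param rotation `"none"` (h-w plane), `"swap_w_N"` (N-w plane) or
#'   `"swap_h_N"` (h-N plane).
#' @param weights list with `W` (98 x 1 convolution matrix), `bn.g`, `bn.b`;
#'   randomly initialized from `seed` when omitted.
#' @param seed seed for default weights.
#' @return Gated feature array, same shape as `t`.
#' @export
triplet_branch <- function(t, rotation = c("none", "swap_w_N", "swap_h_N"),
                           weights = NULL, seed = 0) {
  rotation <- match.arg(rotation)
  stopifnot(is.array(t), length(dim(t)) == 3)
  if (is.null(weights)) weights <- trip_branch_init(seed)
  perm <- triplet_perms[[rotation]]
  xp <- if (all(perm == 1:3)) t else aperm(t, perm)
  buffers <- list(b.rm = 0, b.rv = 1)
  f <- trip_branch_fwd(xp, weights, buffers, "b", train = TRUE)
  y <- f$y
  if (!all(perm == 1:3)) y <- aperm(y, order(perm))
  y
}

#' Triplet attention
#'
#' Averages the three cross-dimension branches ([triplet_branch()] with each
#' rotation). Shape is preserved.
#'
#' @param t `(h, w, N)` feature array.
#' @param weights optional list of three branch weight lists (order: none,
#'   swap_w_N, swap_h_N).
#' @param seed seed for default weights.
#' @return `(h, w, N)` array, the mean of the three branch outputs.
#' @export
triplet_attention <- function(t, weights = NULL, seed = 0) {
  rot <- names(triplet_perms)
  if (is.null(weights)) weights <- lapply(1:3, function(i) trip_branch_init(derive_seed(seed, i)))
  b <- mapply(function(r, w) triplet_branch(t, r, w), rot, weights, SIMPLIFY = FALSE)
  (b[[1]] + b[[2]] + b[[3]]) / 3
}
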