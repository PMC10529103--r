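# Internal helpers: seeded evaluation, cached bilinear resize, small assertions.

.fba_env <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded internals never
#' perturb the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and stream ids; stays inside 32-bit
# integer range so set.seed() accepts it.
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (v in ids) h <- (h * 69069 + as.numeric(v) + 1) %% 2147483647
  as.integer(h)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Interpolation matrix mapping a length-n axis to length-m by bilinear
# sampling at output pixel centres (half-pixel convention, edge clamped).
interp_matrix <- function(n_in, n_out) {
  key <- paste0("ip_", n_in, "_", n_out)
  m <- .fba_env[[key]]
  if (!is.null(m)) return(m)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  i0 <- floor(src)
  w1 <- src - i0
  i0c <- clamp(i0, 1, n_in)
  i1c <- clamp(i0 + 1, 1, n_in)
  m <- matrix(0, n_out, n_in)
  m[cbind(seq_len(n_out), i0c)] <- m[cbind(seq_len(n_out), i0c)] + (1 - w1)
  m[cbind(seq_len(n_out), i1c)] <- m[cbind(seq_len(n_out), i1c)] + w1
  .fba_env[[key]] <- m
  m
}

# Bilinear resize of an (h, w) matrix or (h, w, c) array.
resize_bilinear <- function(x, out_h, out_w = out_h) {
  d <- dim(x)
  if (length(d) == 2) {
    A <- interp_matrix(d[1], out_h)
    B <- interp_matrix(d[2], out_w)
    return(A %*% x %*% t(B))
  }
  if (length(d) != 3) stopf("resize_bilinear expects a matrix or 3-d array")
  A <- interp_matrix(d[1], out_h)
  Bt <- t(interp_matrix(d[2], out_w))
  out <- array(0, c(out_h, out_w, d[3]))
  for (k in seq_len(d[3])) out[, , k] <- A %*% x[, , k] %*% Bt
  out
}

# Flip an (h, w, c) array; used by both augment() and the training loop.
flip_array <- function(x, horizontal = FALSE, vertical = FALSE) {
  if (horizontal) x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  if (vertical) x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
  x
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)
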