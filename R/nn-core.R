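#' Numeric layer primitives
#'
#' Forward/backward pairs for the layers used by the encoders, fusion and
#' head: affine maps, layer normalization over channels, exact GELU,
#' row-softmax, 2-D depthwise convolution, and patch (de)composition.
#' Each `*_fwd` returns `list(out, cache)`; the matching `*_bwd` takes the
#' upstream gradient and the cache and returns gradients for inputs and
#' parameters. All are pure functions of their arguments, so repeated
#' evaluation is bit-identical. Backward passes are verified against central
#' finite differences in the test suite.
#'
#' @name nn-core
#' @keywords internal
NULL

## ---- affine -------------------------------------------------------------

linear_fwd <- function(X, W, b = NULL) {
  out <- X %*% W
  if (!is.null(b)) out <- sweep(out, 2, b, "+")
  list(out = out, cache = list(X = X, W = W, has_b = !is.null(b)))
}

linear_bwd <- function(dout, cache) {
  list(dX = dout %*% t(cache$W),
       dW = crossprod(cache$X, dout),
       db = if (cache$has_b) colSums(dout) else NULL)
}

## ---- layer normalization (over the channel axis, per token) -------------

ln_fwd <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma))
}

ln_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dout, 2, cache$gamma, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * cache$inv_sd
  list(dX = dX, dgamma = colSums(dout * xhat), dbeta = colSums(dout))
}

## ---- GELU (exact, Phi-based) --------------------------------------------

gelu_fwd <- function(X) {
  list(out = X * stats::pnorm(X), cache = list(X = X))
}

gelu_bwd <- function(dout, cache) {
  X <- cache$X
  list(dX = dout * (stats::pnorm(X) + X * stats::dnorm(X)))
}

## ---- softmax over rows ---------------------------------------------------

softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# gradient through row-softmax: dS = P * (dP - rowSums(dP * P))
softmax_rows_bwd <- function(dP, P) {
  P * (dP - rowSums(dP * P))
}

## ---- depthwise 2-D convolution (same zero padding) ----------------------

# x: h x w x C array; K: k x k x C kernel; bias: length-C or NULL
dwconv_fwd <- function(x, K, bias = NULL) {
  d <- dim(x); h <- d[1]; w <- d[2]; C <- d[3]
  k <- dim(K)[1]; r <- (k - 1L) %/% 2L
  pad <- array(0, c(h + 2 * r, w + 2 * r, C))
  pad[r + seq_len(h), r + seq_len(w), ] <- x
  out <- array(0, c(h, w, C))
  hw <- h * w
  for (a in seq_len(k)) for (b in seq_len(k)) {
    slab <- pad[(a - 1) + seq_len(h), (b - 1) + seq_len(w), , drop = FALSE]
    out <- out + slab * rep(K[a, b, ], each = hw)
  }
  if (!is.null(bias)) out <- out + rep(bias, each = hw)
  list(out = out, cache = list(pad = pad, K = K, h = h, w = w, C = C, k = k,
                               r = r, has_b = !is.null(bias)))
}

dwconv_bwd <- function(dout, cache) {
  h <- cache$h; w <- cache$w; C <- cache$C; k <- cache$k; r <- cache$r
  hw <- h * w
  dpad <- array(0, dim(cache$pad))
  dK <- array(0, c(k, k, C))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    slab <- cache$pad[(a - 1) + seq_len(h), (b - 1) + seq_len(w), , drop = FALSE]
    dK[a, b, ] <- colSums(matrix(slab * dout, hw, C))
    dpad[(a - 1) + seq_len(h), (b - 1) + seq_len(w), ] <-
      dpad[(a - 1) + seq_len(h), (b - 1) + seq_len(w), , drop = FALSE] +
      dout * rep(cache$K[a, b, ], each = hw)
  }
  list(dx = dpad[r + seq_len(h), r + seq_len(w), , drop = FALSE],
       dK = dK,
       db = if (cache$has_b) colSums(matrix(dout, hw, C)) else NULL)
}

## ---- patch (de)composition ----------------------------------------------

.index_cache <- new.env(parent = emptyenv())

memo <- function(key, value_fn) {
  if (is.null(.index_cache[[key]])) .index_cache[[key]] <- value_fn()
  .index_cache[[key]]
}

# linear-index map for extracting non-overlapping p x p patches from an
# h x w x C array into row-major-ordered tokens of length p*p*C
patch_index <- function(h, w, C, p) {
  memo(sprintf("patch_%d_%d_%d_%d", h, w, C, p),
       function() patch_index_compute(h, w, C, p))
}

patch_index_compute <- function(h, w, C, p) {
  stopifnot(h %% p == 0, w %% p == 0)
  hp <- h %/% p; wp <- w %/% p
  ti <- rep(seq_len(hp), each = wp)          # row-major token order
  tj <- rep(seq_len(wp), times = hp)
  A <- (ti - 1L) * p + (tj - 1L) * p * h     # token base offset
  dr <- rep(seq_len(p), times = p * C)
  dc <- rep(rep(seq_len(p), each = p), times = C)
  ch <- rep(seq_len(C), each = p * p)
  B <- dr + (dc - 1L) * h + (ch - 1L) * h * w
  outer(A, B, "+")
}

# h x w x C array -> (hp*wp) x (p*p*C) token matrix, tokens row-major
patchify <- function(x, p) {
  d <- dim(x)
  idx <- patch_index(d[1], d[2], d[3], p)
  # linear (vector) indexing: a bare matrix index would be read as
  # coordinate rows whenever ncol(idx) equals the array rank
  matrix(x[as.vector(idx)], nrow(idx), ncol(idx))
}

# inverse of patchify: token matrix -> h x w x C array
unpatchify <- function(tokens, h, w, C, p) {
  idx <- patch_index(h, w, C, p)
  x <- array(0, c(h, w, C))
  x[as.vector(idx)] <- as.vector(tokens)
  x
}

# tokens (n x C, row-major over an h x w grid) <-> spatial array
tokens_to_grid <- function(tokens, h, w) unpatchify(tokens, h, w, ncol(tokens), 1L)
grid_to_tokens <- function(x) patchify(x, 1L)

## ---- parameter-tree utilities -------------------------------------------

# parameters are nested named lists of numeric arrays; these walk two trees
# in parallel (used by AdamW, EMA, and gradient accumulation)
tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(t) tree_map(f, t)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    stopifnot(is.list(b), identical(names(a), names(b)))
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    out
  } else {
    f(a, b)
  }
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_sum_sq <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, tree_sum_sq, numeric(1))) else sum(tree^2)
}

# flatten to a single numeric vector (stable order) and back; used for
# finite-difference checks and checkpoint hashing
tree_flatten <- function(tree) {
  if (is.list(tree)) unlist(lapply(tree, tree_flatten), use.names = FALSE)
  else as.numeric(tree)
}

tree_unflatten <- function(tree, values) {
  pos <- 0L
  rebuild <- function(t) {
    if (is.list(t)) return(lapply(t, rebuild))
    n <- length(t)
    out <- t
    out[] <- values[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  rebuild(tree)
}

## ---- initializers --------------------------------------------------------

init_mat <- function(nin, nout, scale = sqrt(2 / (nin + nout))) {
  matrix(stats::rnorm(nin * nout, sd = scale), nin, nout)
}
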