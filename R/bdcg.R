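#' Bi-directional cross-guidance fusion
#'
#' Reciprocal multi-head cross-attention between the local feature grid and
#' the global token sequence: the local stream queries the global stream and
#' vice versa, each refined stream is layer-normalized after its residual,
#' and the two refined streams are mean-pooled and concatenated (local
#' first) into the fused vector Z. Both pathways read the *raw* streams
#' (they run in parallel, not sequentially). Attention here is plain scaled
#' dot-product softmax; cosine attention is reserved for the global encoder.
#'
#' @name bdcg
NULL

#' Flatten a spatial feature grid into tokens (and back)
#'
#' Row-major: token `i` (1-based) corresponds to grid cell
#' `((i-1) %/% w + 1, (i-1) %% w + 1)`.
#'
#' @param F_L `h x w x C` array.
#' @return list with `tokens` (`(h*w) x C`), `h`, `w`.
#' @export
tokenize_local <- function(F_L) {
  d <- dim(F_L)
  list(tokens = grid_to_tokens(F_L), h = d[1], w = d[2])
}

#' @rdname tokenize_local
#' @param tokens token matrix from [tokenize_local()].
#' @param h,w original grid shape.
#' @export
detokenize_local <- function(tokens, h, w) tokens_to_grid(tokens, h, w)

init_mca <- function(C_q, C_kv, n_heads, d_head) {
  hd <- n_heads * d_head
  list(Wq = init_mat(C_q, hd), bq = rep(0, hd),
       Wk = init_mat(C_kv, hd), bk = rep(0, hd),
       Wv = init_mat(C_kv, hd), bv = rep(0, hd),
       Wo = init_mat(hd, C_q) * 0.5, bo = rep(0, C_q),
       ln_g = rep(1, C_q), ln_b = rep(0, C_q))
}

# scaled dot-product attention per head over projected tokens
mca_fwd <- function(Xq, Xkv, params, n_heads, d_head) {
  q <- linear_fwd(Xq, params$Wq, params$bq)
  k <- linear_fwd(Xkv, params$Wk, params$bk)
  v <- linear_fwd(Xkv, params$Wv, params$bv)
  nq <- nrow(Xq)
  pre <- matrix(0, nq, n_heads * d_head)
  heads <- vector("list", n_heads)
  for (hd in seq_len(n_heads)) {
    cs <- (hd - 1L) * d_head
    Q <- q$out[, cs + seq_len(d_head), drop = FALSE]
    K <- k$out[, cs + seq_len(d_head), drop = FALSE]
    V <- v$out[, cs + seq_len(d_head), drop = FALSE]
    S <- Q %*% t(K) / sqrt(d_head)
    P <- softmax_rows(S)
    pre[, cs + seq_len(d_head)] <- P %*% V
    heads[[hd]] <- list(P = P, Q = Q, K = K, V = V)
  }
  o <- linear_fwd(pre, params$Wo, params$bo)
  list(out = o$out, pre_proj = pre, weights = lapply(heads, `[[`, "P"),
       cache = list(q = q$cache, k = k$cache, v = v$cache, o = o$cache,
                    heads = heads, n_heads = n_heads, d_head = d_head))
}

mca_bwd <- function(dout, cache) {
  n_heads <- cache$n_heads; d_head <- cache$d_head
  bo <- linear_bwd(dout, cache$o)
  dq_all <- matrix(0, nrow(cache$heads[[1]]$Q), n_heads * d_head)
  dk_all <- matrix(0, nrow(cache$heads[[1]]$K), n_heads * d_head)
  dv_all <- dk_all
  for (hd in seq_len(n_heads)) {
    cs <- (hd - 1L) * d_head
    hc <- cache$heads[[hd]]
    dpre <- bo$dX[, cs + seq_len(d_head), drop = FALSE]
    dP <- dpre %*% t(hc$V)
    dV <- crossprod(hc$P, dpre)
    dS <- softmax_rows_bwd(dP, hc$P) / sqrt(d_head)
    dq_all[, cs + seq_len(d_head)] <- dS %*% hc$K
    dk_all[, cs + seq_len(d_head)] <- crossprod(dS, hc$Q)
    dv_all[, cs + seq_len(d_head)] <- dV
  }
  bq <- linear_bwd(dq_all, cache$q)
  bk <- linear_bwd(dk_all, cache$k)
  bv <- linear_bwd(dv_all, cache$v)
  list(dXq = bq$dX, dXkv = bk$dX + bv$dX,
       dparams = list(Wq = bq$dW, bq = bq$db, Wk = bk$dW, bk = bk$db,
                      Wv = bv$dW, bv = bv$db, Wo = bo$dW, bo = bo$db))
}

#' Multi-head cross-attention between two token streams
#'
#' Per head, `softmax(Q K' / sqrt(d_head)) V` with queries projected from
#' `x_query` and keys/values from `x_context`; head outputs are concatenated
#' and linearly projected back to the query stream's channel width. The
#' output therefore always has the query stream's token count and width.
#'
#' @param x_query `n_q x C_q` token matrix.
#' @param x_context `n_kv x C_kv` token matrix.
#' @param params projection parameters (see `init_mca`).
#' @param n_heads,d_head head count and per-head width.
#' @return list with `out` (`n_q x C_q`), `pre_proj` (concatenated head
#'   outputs before the output projection), and `weights` (one attention
#'   matrix per head, rows summing to 1).
#' @export
multi_head_cross_attention <- function(x_query, x_context, params,
                                       n_heads, d_head) {
  f <- mca_fwd(x_query, x_context, params, n_heads, d_head)
  list(out = f$out, pre_proj = f$pre_proj, weights = f$weights)
}

#' Initialize the fusion module
#'
#' @param C_L,C_G channel widths of the local and global streams.
#' @param n_heads,d_head cross-attention geometry.
#' @param seed optional seed.
#' @return parameter list with pathways `g2l` (local queries, global
#'   keys/values) and `l2g` (roles swapped).
#' @export
init_bdcg <- function(C_L, C_G, n_heads = 8L, d_head = 128L, seed = NULL) {
  with_seed(seed, list(g2l = init_mca(C_L, C_G, n_heads, d_head),
                       l2g = init_mca(C_G, C_L, n_heads, d_head)))
}

# one pathway: refined = LN(X + MCA(X, context)); enable = FALSE drops the
# attention branch (passive-fusion reduction) but keeps the LN
refine_fwd <- function(X, context, pw, n_heads, d_head, enable = TRUE) {
  if (enable) {
    at <- mca_fwd(X, context, pw, n_heads, d_head)
    r <- X + at$out
  } else {
    at <- NULL
    r <- X
  }
  ln <- ln_fwd(r, pw$ln_g, pw$ln_b)
  list(out = ln$out, cache = list(at = at, ln = ln$cache, enable = enable))
}

refine_bwd <- function(dout, cache, pw) {
  bl <- ln_bwd(dout, cache$ln)
  if (cache$enable) {
    ba <- mca_bwd(bl$dX, cache$at$cache)
    dX <- bl$dX + ba$dXq
    dcontext <- ba$dXkv
    dpw <- c(ba$dparams, list(ln_g = bl$dgamma, ln_b = bl$dbeta))
  } else {
    dX <- bl$dX
    dcontext <- NULL
    dpw <- tree_zeros_like(pw)
    dpw$ln_g <- bl$dgamma
    dpw$ln_b <- bl$dbeta
  }
  dpw <- dpw[names(pw)]
  list(dX = dX, dcontext = dcontext, dparams = dpw)
}

#' Refine the local stream against the global stream
#'
#' `F'_L = LN(F_L + MCA(Q_L, K_G, V_G))`: the local tokens query the global
#' tokens, the attention output is added back in the local stream's native
#' width, and the sum is layer-normalized.
#'
#' @param FL_tokens,FG_tokens token matrices of the two streams.
#' @param params fusion parameters from [init_bdcg()].
#' @param n_heads head count (per-head width is inferred from the
#'   projection shape).
#' @return refined token matrix, same shape as the query stream.
#' @export
global_to_local_refine <- function(FL_tokens, FG_tokens, params, n_heads = 2L) {
  d_head <- ncol(params$g2l$Wq) %/% n_heads
  refine_fwd(FL_tokens, FG_tokens, params$g2l, n_heads, d_head)$out
}

#' Refine the global stream against the local stream
#'
#' Mirror of [global_to_local_refine()] with roles swapped:
#' `F'_G = LN(F_G + MCA(Q_G, K_L, V_L))`.
#' @inheritParams global_to_local_refine
#' @export
local_to_global_refine <- function(FG_tokens, FL_tokens, params, n_heads = 2L) {
  d_head <- ncol(params$l2g$Wq) %/% n_heads
  refine_fwd(FG_tokens, FL_tokens, params$l2g, n_heads, d_head)$out
}

# bilinear per-channel alignment of a token grid to a target resolution
align_grid <- function(grid, th, tw) {
  d <- dim(grid)
  if (d[1] == th && d[2] == tw) return(grid)
  out <- array(0, c(th, tw, d[3]))
  for (ch in seq_len(d[3])) {
    g <- grid[, , ch]
    lo <- min(g); hi <- max(g)
    if (hi == lo) { out[, , ch] <- lo; next }
    out[, , ch] <- resize_to_input((g - lo) / (hi - lo), c(th, tw)) * (hi - lo) + lo
  }
  out
}

#' Concatenate and pool the refined streams
#'
#' Each refined stream is mean-pooled over its tokens and the two pooled
#' vectors are concatenated local-first into the fused vector Z of length
#' `C_L + C_G`. The channel-concatenated spatial map (streams aligned by
#' bilinear interpolation when their grids differ) is returned alongside for
#' saliency.
#'
#' @param FLp,FGp refined token matrices.
#' @param hw_L,hw_G grid shapes `(h, w)` of the two streams.
#' @return list with `Z` (numeric vector), `map` (`h x w x (C_L + C_G)`
#'   array), and `C_L`.
#' @export
fuse_concat_pool <- function(FLp, FGp, hw_L, hw_G) {
  Z <- c(colMeans(FLp), colMeans(FGp))
  gl <- tokens_to_grid(FLp, hw_L[1], hw_L[2])
  gg <- tokens_to_grid(FGp, hw_G[1], hw_G[2])
  th <- max(hw_L[1], hw_G[1]); tw <- max(hw_L[2], hw_G[2])
  gl <- align_grid(gl, th, tw); gg <- align_grid(gg, th, tw)
  map <- array(c(gl, gg), c(th, tw, ncol(FLp) + ncol(FGp)))
  list(Z = Z, map = map, C_L = ncol(FLp))
}

# full fusion stage with cache: raw streams in, Z + spatial map out
bdcg_fwd <- function(FL_tokens, FG_tokens, hw_L, hw_G, params,
                     n_heads, d_head, enable = TRUE) {
  rl <- refine_fwd(FL_tokens, FG_tokens, params$g2l, n_heads, d_head, enable)
  rg <- refine_fwd(FG_tokens, FL_tokens, params$l2g, n_heads, d_head, enable)
  fz <- fuse_concat_pool(rl$out, rg$out, hw_L, hw_G)
  list(Z = fz$Z, map = fz$map, C_L = fz$C_L,
       FLp = rl$out, FGp = rg$out,
       cache = list(rl = rl$cache, rg = rg$cache,
                    n_L = nrow(FL_tokens), n_G = nrow(FG_tokens),
                    C_Lw = ncol(FL_tokens), C_Gw = ncol(FG_tokens)))
}

# backward from dZ to both raw streams and the fusion parameters
bdcg_bwd <- function(dZ, cache, params) {
  C_L <- cache$C_Lw; C_G <- cache$C_Gw
  dFLp <- matrix(dZ[seq_len(C_L)], cache$n_L, C_L, byrow = TRUE) / cache$n_L
  dFGp <- matrix(dZ[C_L + seq_len(C_G)], cache$n_G, C_G, byrow = TRUE) / cache$n_G
  bl <- refine_bwd(dFLp, cache$rl, params$g2l)
  bg <- refine_bwd(dFGp, cache$rg, params$l2g)
  dFL <- bl$dX
  dFG <- bg$dX
  if (!is.null(bg$dcontext)) dFL <- dFL + bg$dcontext
  if (!is.null(bl$dcontext)) dFG <- dFG + bl$dcontext
  list(dFL = dFL, dFG = dFG,
       dparams = list(g2l = bl$dparams, l2g = bg$dparams))
}
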