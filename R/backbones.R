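#' Backbone presets
#'
#' Named configurations for the two encoders. Every preset keeps both
#' streams at the same final grid (stem/embed stride 4, one 2x reduction per
#' extra stage) so the fused spatial map needs no resampling. The `base`
#' preset carries the reference dimensions (384x384 input, final channel
#' width 1024 per stream, 7x7 attention windows, 8 fusion heads of width
#' 128, fused dimension 2048) with shallow per-stage depth so a CPU forward
#' pass stays tractable; `tiny` (96x96) and `micro` (48x48) are the
#' desk-scale presets used throughout the tests.
#'
#' @param name one of `"micro"`, `"tiny"`, `"base"`.
#' @return a list of architecture fields (`input_size`, per-stream stage
#'   channels/depths, window size, head counts, fusion dims).
#' @export
backbone_preset <- function(name = c("tiny", "micro", "base")) {
  name <- match.arg(name)
  switch(name,
    micro = list(
      name = "micro", input_size = 48L, patch = 6L,
      local_channels = c(8L, 16L), local_depths = c(1L, 1L), dw_kernel = 5L,
      global_channels = c(8L, 16L), global_depths = c(2L, 2L),
      window = 4L, global_heads = c(1L, 2L),
      fusion_heads = 2L, fusion_d_head = 8L),
    tiny = list(
      name = "tiny", input_size = 96L, patch = 6L,
      local_channels = c(16L, 32L), local_depths = c(1L, 1L), dw_kernel = 7L,
      global_channels = c(16L, 32L), global_depths = c(2L, 2L),
      window = 4L, global_heads = c(2L, 2L),
      fusion_heads = 2L, fusion_d_head = 16L),
    base = list(
      name = "base", input_size = 384L, patch = 4L,
      local_channels = c(128L, 256L, 512L, 1024L), local_depths = c(1L, 1L, 1L, 1L),
      dw_kernel = 7L,
      global_channels = c(128L, 256L, 512L, 1024L), global_depths = c(2L, 2L, 2L, 2L),
      window = 7L, global_heads = c(4L, 8L, 16L, 32L),
      fusion_heads = 8L, fusion_d_head = 128L))
}

# total stride of either stream
preset_stride <- function(preset)
  as.integer(preset$patch * 2^(length(preset$local_channels) - 1))

## ======================================================================
## Local encoder: 7x7 depthwise-conv inverted-bottleneck blocks with LN
## ======================================================================

init_convnext_block <- function(C, k) {
  list(dw = array(stats::rnorm(k * k * C, sd = sqrt(2 / (k * k))), c(k, k, C)),
       dwb = rep(0, C),
       ln_g = rep(1, C), ln_b = rep(0, C),
       W1 = init_mat(C, 4L * C), b1 = rep(0, 4L * C),
       W2 = init_mat(4L * C, C) * 0.5, b2 = rep(0, C))
}

#' One local-encoder block (forward with cache)
#'
#' Depthwise k x k convolution (same padding), layer normalization over
#' channels, pointwise expansion to 4C, nonlinearity, pointwise projection
#' back to C, and a residual connection — the inverted-bottleneck design
#' with the wide depthwise kernel carrying all spatial mixing.
#'
#' @param x `h x w x C` array.
#' @param params block parameter list (see `init_convnext_block`).
#' @param use_ln disable to bypass the normalization (diagnostics only).
#' @param act `"gelu"` (default) or `"identity"`.
#' @return `h x w x C` array.
#' @export
convnext_block <- function(x, params, use_ln = TRUE, act = "gelu") {
  convnext_block_fwd(x, params, use_ln, act)$out
}

convnext_block_fwd <- function(x, params, use_ln = TRUE, act = "gelu") {
  d <- dim(x)
  if (dim(params$dw)[3] != d[3]) stop("convnext_block: channel mismatch")
  cv <- dwconv_fwd(x, params$dw, params$dwb)
  tok <- grid_to_tokens(cv$out)
  if (use_ln) {
    ln <- ln_fwd(tok, params$ln_g, params$ln_b)
    t1 <- ln$out
  } else {
    ln <- NULL; t1 <- tok
  }
  l1 <- linear_fwd(t1, params$W1, params$b1)
  if (act == "gelu") { g <- gelu_fwd(l1$out); t2 <- g$out } else { g <- NULL; t2 <- l1$out }
  l2 <- linear_fwd(t2, params$W2, params$b2)
  out <- x + unpatchify(l2$out, d[1], d[2], d[3], 1L)
  list(out = out,
       cache = list(cv = cv$cache, ln = ln$cache %||% NULL, l1 = l1$cache,
                    g = if (!is.null(g)) g$cache else NULL, l2 = l2$cache,
                    dims = d, use_ln = use_ln, act = act))
}

convnext_block_bwd <- function(dout, cache) {
  d <- cache$dims
  dtok_out <- grid_to_tokens(dout)
  b2 <- linear_bwd(dtok_out, cache$l2)
  dt2 <- b2$dX
  if (cache$act == "gelu") dt2 <- gelu_bwd(dt2, cache$g)$dX
  b1 <- linear_bwd(dt2, cache$l1)
  if (cache$use_ln) {
    bl <- ln_bwd(b1$dX, cache$ln)
    dtok <- bl$dX; dg <- bl$dgamma; db <- bl$dbeta
  } else {
    dtok <- b1$dX; dg <- numeric(d[3]) * 0; db <- numeric(d[3]) * 0
  }
  bc <- dwconv_bwd(tokens_to_grid(dtok, d[1], d[2]), cache$cv)
  list(dx = dout + bc$dx,
       dparams = list(dw = bc$dK, dwb = bc$db, ln_g = dg, ln_b = db,
                      W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db))
}

init_local_encoder <- function(preset, in_ch = 1L) {
  p <- preset$patch
  C <- preset$local_channels
  stages <- vector("list", length(C))
  for (s in seq_along(C)) {
    blocks <- lapply(seq_len(preset$local_depths[s]),
                     function(i) init_convnext_block(C[s], preset$dw_kernel))
    down <- if (s > 1) {
      list(ln_g = rep(1, C[s - 1]), ln_b = rep(0, C[s - 1]),
           W = init_mat(4L * C[s - 1], C[s]), b = rep(0, C[s]))
    } else NULL
    stages[[s]] <- list(blocks = blocks, down = down)
  }
  list(stem = list(W = init_mat(p * p * in_ch, C[1]), b = rep(0, C[1]),
                   ln_g = rep(1, C[1]), ln_b = rep(0, C[1])),
       stages = stages)
}

#' Local-texture encoding (forward with cache)
#'
#' Patchified stem, then stages of inverted-bottleneck blocks with a 2x
#' patch-merging downsample between stages; returns the final-stage spatial
#' feature map (the "stage-4" output in the reference dimensions).
#' @noRd
local_encode_fwd <- function(image, params, preset) {
  H <- nrow(image); W <- ncol(image)
  stride <- preset_stride(preset)
  if (H %% stride != 0 || W %% stride != 0)
    stop("input size not divisible by total stride ", stride)
  x <- array(image, c(H, W, 1L))
  tok <- patchify(x, preset$patch)
  st <- linear_fwd(tok, params$stem$W, params$stem$b)
  sln <- ln_fwd(st$out, params$stem$ln_g, params$stem$ln_b)
  h <- H %/% preset$patch; w <- W %/% preset$patch
  g <- tokens_to_grid(sln$out, h, w)
  caches <- list(stem = st$cache, stem_ln = sln$cache, stem_hw = c(h, w))
  stage_caches <- vector("list", length(params$stages))
  for (s in seq_along(params$stages)) {
    sc <- list()
    if (s > 1) {
      dn <- params$stages[[s]]$down
      tk <- grid_to_tokens(g)
      dl <- ln_fwd(tk, dn$ln_g, dn$ln_b)
      gi <- tokens_to_grid(dl$out, h, w)
      mg <- patchify(gi, 2L)
      ml <- linear_fwd(mg, dn$W, dn$b)
      h <- h %/% 2L; w <- w %/% 2L
      g <- tokens_to_grid(ml$out, h, w)
      sc$down <- list(ln = dl$cache, lin = ml$cache, hw_in = c(h * 2L, w * 2L))
    }
    sc$blocks <- vector("list", length(params$stages[[s]]$blocks))
    for (b in seq_along(params$stages[[s]]$blocks)) {
      bf <- convnext_block_fwd(g, params$stages[[s]]$blocks[[b]])
      g <- bf$out
      sc$blocks[[b]] <- bf$cache
    }
    stage_caches[[s]] <- sc
  }
  caches$stages <- stage_caches
  caches$final_hw <- c(h, w)
  list(out = g, cache = caches)
}

local_encode_bwd <- function(dout, cache, params, preset) {
  g <- dout
  dstages <- vector("list", length(params$stages))
  for (s in rev(seq_along(params$stages))) {
    sc <- cache$stages[[s]]
    dblocks <- vector("list", length(sc$blocks))
    for (b in rev(seq_along(sc$blocks))) {
      bb <- convnext_block_bwd(g, sc$blocks[[b]])
      g <- bb$dx
      dblocks[[b]] <- bb$dparams
    }
    ddown <- NULL
    if (s > 1) {
      hw_in <- sc$down$hw_in
      dtok <- grid_to_tokens(g)
      bl <- linear_bwd(dtok, sc$down$lin)
      dgi <- unpatchify(bl$dX, hw_in[1], hw_in[2],
                        length(params$stages[[s]]$down$ln_g), 2L)
      bln <- ln_bwd(grid_to_tokens(dgi), sc$down$ln)
      g <- tokens_to_grid(bln$dX, hw_in[1], hw_in[2])
      ddown <- list(ln_g = bln$dgamma, ln_b = bln$dbeta, W = bl$dW, b = bl$db)
    }
    dstages[[s]] <- list(blocks = dblocks, down = ddown)
  }
  hw <- cache$stem_hw
  bsl <- ln_bwd(grid_to_tokens(g), cache$stem_ln)
  bst <- linear_bwd(bsl$dX, cache$stem)
  list(dparams = list(stem = list(W = bst$dW, b = bst$db,
                                  ln_g = bsl$dgamma, ln_b = bsl$dbeta),
                      stages = dstages))
}

#' Encode an image with the local-texture stream
#'
#' @param image preprocessed image matrix matching the preset input size.
#' @param params parameters from [init_backbones()]`$local`.
#' @param preset a [backbone_preset()].
#' @return the final-stage feature map as an `h x w x C` array with
#'   attribute `stride`.
#' @export
local_encode <- function(image, params, preset) {
  f <- local_encode_fwd(image, params, preset)
  structure(f$out, stride = preset_stride(preset))
}

## ======================================================================
## Window utilities
## ======================================================================

# row-major token ids of each M x M window over an h x w grid
win_index <- function(h, w, M) {
  memo(sprintf("win_%d_%d_%d", h, w, M), function() win_index_compute(h, w, M))
}

win_index_compute <- function(h, w, M) {
  stopifnot(h %% M == 0, w %% M == 0)
  nwr <- h %/% M; nwc <- w %/% M
  idx <- matrix(0L, nwr * nwc, M * M)
  wI <- 1L
  for (wr in seq_len(nwr)) for (wc in seq_len(nwc)) {
    rows <- (wr - 1L) * M + seq_len(M)
    cols <- (wc - 1L) * M + seq_len(M)
    idx[wI, ] <- as.vector(t(outer((rows - 1L) * w, cols, "+")))
    wI <- wI + 1L
  }
  idx
}

#' Partition a token grid into non-overlapping windows
#'
#' Tokens are row-major over an `h x w` grid. Returns one `M^2 x C` matrix
#' per window; [window_reverse()] inverts the rearrangement exactly.
#'
#' @param tokens `n x C` matrix, `n = h * w`.
#' @param h,w grid shape (must be multiples of `M`).
#' @param M window side length.
#' @return list of `M^2 x C` matrices, windows in row-major order.
#' @export
window_partition <- function(tokens, h, w, M) {
  idx <- win_index(h, w, M)
  lapply(seq_len(nrow(idx)), function(i) tokens[idx[i, ], , drop = FALSE])
}

#' @rdname window_partition
#' @param windows list of `M^2 x C` window matrices.
#' @export
window_reverse <- function(windows, h, w, M) {
  idx <- win_index(h, w, M)
  C <- ncol(windows[[1]])
  tokens <- matrix(0, h * w, C)
  for (i in seq_along(windows)) tokens[idx[i, ], ] <- windows[[i]]
  tokens
}

# cyclic roll of row-major grid tokens by (s, s) toward the origin
roll_tokens <- function(tokens, h, w, s) {
  if (s == 0) return(tokens)
  ri <- ((seq_len(h) - 1L + s) %% h) + 1L
  ci <- ((seq_len(w) - 1L + s) %% w) + 1L
  ord <- as.vector(t(outer((ri - 1L) * w, ci, "+")))
  tokens[ord, , drop = FALSE]
}

# relative-position index (M^2 x M^2) into a (2M-1)^2 bias table
rel_pos_index <- function(M) {
  memo(sprintf("rpi_%d", M), function() rel_pos_index_compute(M))
}

rel_pos_index_compute <- function(M) {
  pos <- expand.grid(c = seq_len(M), r = seq_len(M))  # row-major token order
  dr <- outer(pos$r, pos$r, "-") + M
  dc <- outer(pos$c, pos$c, "-") + M
  (dr - 1L) * (2L * M - 1L) + dc
}

# additive attention masks for shifted windows over a padded grid:
# tokens in different pre-shift neighborhoods (or padding) must not attend
sw_masks <- function(hp, wp, M, shift, h_real, w_real) {
  memo(sprintf("mask_%d_%d_%d_%d_%d_%d", hp, wp, M, shift, h_real, w_real),
       function() sw_masks_compute(hp, wp, M, shift, h_real, w_real))
}

sw_masks_compute <- function(hp, wp, M, shift, h_real, w_real) {
  seg <- function(n) {
    s <- integer(n)
    if (shift > 0) {
      s[seq_len(n)] <- 0L
      s[n - M + seq_len(M)] <- 1L
      s[n - shift + seq_len(shift)] <- 2L
    }
    s
  }
  sr <- seg(hp); sc <- seg(wp)
  id <- outer(sr * 3L, sc, "+")                 # hp x wp region ids
  id[seq_len(hp) > h_real, ] <- -1L             # padding gets its own id
  id[, seq_len(wp) > w_real] <- -1L
  idt <- matrix(as.vector(t(id)), ncol = 1)     # row-major token ids
  if (shift > 0) idt <- roll_tokens(idt, hp, wp, shift)
  idx <- win_index(hp, wp, M)
  lapply(seq_len(nrow(idx)), function(i) {
    v <- idt[idx[i, ], 1]
    m <- matrix(0, length(v), length(v))
    m[outer(v, v, "!=")] <- -1e9
    m
  })
}

## ======================================================================
## Scaled cosine attention
## ======================================================================

l2norm_rows_fwd <- function(X, eps = 1e-12) {
  n <- sqrt(rowSums(X^2))
  safe <- n > eps
  Xh <- X / ifelse(safe, n, 1)
  Xh[!safe, ] <- 0                              # zero-norm guard: cosine = 0
  list(out = Xh, cache = list(Xh = Xh, n = n, safe = safe))
}

l2norm_rows_bwd <- function(dXh, cache) {
  d <- (dXh - cache$Xh * rowSums(dXh * cache$Xh)) / ifelse(cache$safe, cache$n, 1)
  d[!cache$safe, ] <- 0
  d
}

TAU_MIN <- 0.01

#' Scaled cosine attention (single head)
#'
#' Attention logits are the cosine similarity between query and key rows
#' divided by a positive temperature `tau` (clamped below at 0.01), plus an
#' optional additive bias; rows are softmax-normalized and applied to the
#' values. Zero-norm queries or keys contribute cosine 0.
#'
#' @param Q,K,V matrices `nq x d`, `nk x d`, `nk x dv`.
#' @param tau positive scalar temperature.
#' @param bias optional `nq x nk` additive logit matrix.
#' @return list with `out` (`nq x dv`) and `weights` (`nq x nk`, rows sum
#'   to 1).
#' @export
scaled_cosine_attention <- function(Q, K, V, tau, bias = NULL) {
  stopifnot(tau > 0, ncol(Q) == ncol(K), nrow(K) == nrow(V))
  f <- cos_attn_fwd(Q, K, V, tau, bias, mask = NULL)
  list(out = f$out, weights = f$cache$P)
}

cos_attn_fwd <- function(Q, K, V, tau, bias = NULL, mask = NULL) {
  tauc <- max(tau, TAU_MIN)
  qn <- l2norm_rows_fwd(Q); kn <- l2norm_rows_fwd(K)
  Ccos <- qn$out %*% t(kn$out)
  S <- Ccos / tauc
  if (!is.null(bias)) S <- S + bias
  if (!is.null(mask)) S <- S + mask
  P <- softmax_rows(S)
  out <- P %*% V
  list(out = out,
       cache = list(qn = qn$cache, kn = kn$cache, Ccos = Ccos, P = P, V = V,
                    tau = tau, tauc = tauc))
}

cos_attn_bwd <- function(dout, cache) {
  P <- cache$P
  dP <- dout %*% t(cache$V)
  dV <- crossprod(P, dout)
  dS <- softmax_rows_bwd(dP, P)
  dbias <- dS
  dC <- dS / cache$tauc
  dtau <- if (cache$tau > TAU_MIN) -sum(dS * cache$Ccos) / cache$tauc^2 else 0
  dQh <- dC %*% cache$kn$Xh
  dKh <- crossprod(dC, cache$qn$Xh)
  list(dQ = l2norm_rows_bwd(dQh, cache$qn),
       dK = l2norm_rows_bwd(dKh, cache$kn),
       dV = dV, dtau = dtau, dbias = dbias)
}

## ======================================================================
## Shifted-window attention block
## ======================================================================

init_sw_block <- function(C, M, n_heads) {
  list(Wqkv = init_mat(C, 3L * C), bqkv = rep(0, 3L * C),
       Wp = init_mat(C, C), bp = rep(0, C),
       tau = rep(0.3, n_heads),
       bias_table = matrix(stats::rnorm((2L * M - 1L)^2 * n_heads, sd = 0.02),
                           (2L * M - 1L)^2, n_heads),
       ln1_g = rep(1, C), ln1_b = rep(0, C),
       ln2_g = rep(1, C), ln2_b = rep(0, C),
       W1 = init_mat(C, 4L * C), b1 = rep(0, 4L * C),
       W2 = init_mat(4L * C, C) * 0.5, b2 = rep(0, C))
}

#' Shifted-window multi-head cosine-attention block (forward with cache)
#'
#' Optional cyclic shift by floor(M/2), window partition, per-window
#' multi-head scaled cosine attention with relative position bias and
#' cross-window masking of wrapped (and padded) positions, reverse,
#' residual + LN, then a 4x MLP with residual + LN (post-norm placement).
#' @noRd
sw_block_fwd <- function(tokens, h, w, params, M, n_heads, shift = FALSE) {
  C <- ncol(tokens)
  d_head <- C %/% n_heads
  s <- if (shift) M %/% 2L else 0L
  hp <- ceiling(h / M) * M; wp <- ceiling(w / M) * M

  qkv <- linear_fwd(tokens, params$Wqkv, params$bqkv)
  # pad to window multiples (row-major grid), then roll
  pad_map <- as.vector(t(outer((seq_len(h) - 1L) * wp, seq_len(w), "+")))
  padded <- matrix(0, hp * wp, 3L * C)
  padded[pad_map, ] <- qkv$out
  rolled <- roll_tokens(padded, hp, wp, s)
  idx <- win_index(hp, wp, M)
  masks <- if (s > 0L || hp != h || wp != w) sw_masks(hp, wp, M, s, h, w) else NULL
  rpi <- rel_pos_index(M)

  n_win <- nrow(idx)
  attn_out <- matrix(0, hp * wp, C)
  # normalize queries and keys per head over all tokens at once (row norms
  # are window-independent), and build each head bias matrix once
  qn <- kn <- vector("list", n_heads)
  biasm <- vector("list", n_heads)
  tauc <- pmax(params$tau, TAU_MIN)
  for (hd in seq_len(n_heads)) {
    cs <- (hd - 1L) * d_head
    qn[[hd]] <- l2norm_rows_fwd(rolled[, cs + seq_len(d_head), drop = FALSE])
    kn[[hd]] <- l2norm_rows_fwd(rolled[, C + cs + seq_len(d_head), drop = FALSE])
    biasm[[hd]] <- matrix(params$bias_table[rpi, hd], M * M, M * M)
  }
  caches <- vector("list", n_win * n_heads)
  for (wi in seq_len(n_win)) {
    widx <- idx[wi, ]
    for (hd in seq_len(n_heads)) {
      cs <- (hd - 1L) * d_head
      Qh <- qn[[hd]]$out[widx, , drop = FALSE]
      Kh <- kn[[hd]]$out[widx, , drop = FALSE]
      V <- rolled[widx, 2L * C + cs + seq_len(d_head), drop = FALSE]
      Ccos <- tcrossprod(Qh, Kh)
      S <- Ccos / tauc[hd] + biasm[[hd]]
      if (!is.null(masks)) S <- S + masks[[wi]]
      P <- softmax_rows(S)
      attn_out[widx, cs + seq_len(d_head)] <- P %*% V
      caches[[(wi - 1L) * n_heads + hd]] <- list(P = P, Ccos = Ccos, V = V)
    }
  }
  unrolled <- roll_tokens(attn_out, hp, wp, -s)
  attn_tok <- unrolled[pad_map, , drop = FALSE]
  pr <- linear_fwd(attn_tok, params$Wp, params$bp)
  r1 <- tokens + pr$out
  n1 <- ln_fwd(r1, params$ln1_g, params$ln1_b)
  m1 <- linear_fwd(n1$out, params$W1, params$b1)
  gl <- gelu_fwd(m1$out)
  m2 <- linear_fwd(gl$out, params$W2, params$b2)
  r2 <- n1$out + m2$out
  n2 <- ln_fwd(r2, params$ln2_g, params$ln2_b)
  list(out = n2$out,
       cache = list(qkv = qkv$cache, attn = caches, qn = qn, kn = kn,
                    idx = idx, rpi = rpi,
                    pad_map = pad_map, hp = hp, wp = wp, s = s, C = C,
                    n_heads = n_heads, d_head = d_head, M = M,
                    pr = pr$cache, n1 = n1$cache, m1 = m1$cache, gl = gl$cache,
                    m2 = m2$cache, n2 = n2$cache))
}

sw_block_bwd <- function(dout, cache, params) {
  C <- cache$C; n_heads <- cache$n_heads; d_head <- cache$d_head
  M <- cache$M; idx <- cache$idx; s <- cache$s
  hp <- cache$hp; wp <- cache$wp

  bn2 <- ln_bwd(dout, cache$n2)
  dr2 <- bn2$dX
  bm2 <- linear_bwd(dr2, cache$m2)
  bgl <- gelu_bwd(bm2$dX, cache$gl)
  bm1 <- linear_bwd(bgl$dX, cache$m1)
  dn1_out <- dr2 + bm1$dX
  bn1 <- ln_bwd(dn1_out, cache$n1)
  dr1 <- bn1$dX
  dtokens <- dr1
  bpr <- linear_bwd(dr1, cache$pr)

  dunrolled <- matrix(0, hp * wp, C)
  dunrolled[cache$pad_map, ] <- bpr$dX
  dattn_out <- roll_tokens(dunrolled, hp, wp, s)   # inverse of roll by -s

  dqkv_rolled <- matrix(0, hp * wp, 3L * C)
  dtau <- numeric(n_heads)
  dbias_table <- matrix(0, nrow(params$bias_table), n_heads)
  rpi_v <- as.vector(cache$rpi)
  tauc <- pmax(params$tau, TAU_MIN)
  nt <- hp * wp
  for (hd in seq_len(n_heads)) {
    cs <- (hd - 1L) * d_head
    dQh <- matrix(0, nt, d_head)
    dKh <- matrix(0, nt, d_head)
    dbias_sum <- 0
    for (wi in seq_len(nrow(idx))) {
      widx <- idx[wi, ]
      ac <- cache$attn[[(wi - 1L) * n_heads + hd]]
      dout_w <- dattn_out[widx, cs + seq_len(d_head), drop = FALSE]
      dP <- tcrossprod(dout_w, ac$V)
      dS <- softmax_rows_bwd(dP, ac$P)
      dbias_sum <- dbias_sum + dS
      if (params$tau[hd] > TAU_MIN)
        dtau[hd] <- dtau[hd] - sum(dS * ac$Ccos) / tauc[hd]^2
      dC <- dS / tauc[hd]
      dQh[widx, ] <- dQh[widx, , drop = FALSE] +
        dC %*% cache$kn[[hd]]$out[widx, , drop = FALSE]
      dKh[widx, ] <- dKh[widx, , drop = FALSE] +
        crossprod(dC, cache$qn[[hd]]$out[widx, , drop = FALSE])
      dqkv_rolled[widx, 2L * C + cs + seq_len(d_head)] <-
        dqkv_rolled[widx, 2L * C + cs + seq_len(d_head), drop = FALSE] +
        crossprod(ac$P, dout_w)
    }
    dqkv_rolled[, cs + seq_len(d_head)] <- l2norm_rows_bwd(dQh, cache$qn[[hd]]$cache)
    dqkv_rolled[, C + cs + seq_len(d_head)] <- l2norm_rows_bwd(dKh, cache$kn[[hd]]$cache)
    acc <- rowsum(as.vector(dbias_sum), rpi_v)
    dbias_table[as.integer(rownames(acc)), hd] <- acc[, 1]
  }
  dpadded <- roll_tokens(dqkv_rolled, hp, wp, -s)
  dqkv <- dpadded[cache$pad_map, , drop = FALSE]
  bq <- linear_bwd(dqkv, cache$qkv)
  dtokens <- dtokens + bq$dX
  list(dX = dtokens,
       dparams = list(Wqkv = bq$dW, bqkv = bq$db, Wp = bpr$dW, bp = bpr$db,
                      tau = dtau, bias_table = dbias_table,
                      ln1_g = bn1$dgamma, ln1_b = bn1$dbeta,
                      ln2_g = bn2$dgamma, ln2_b = bn2$dbeta,
                      W1 = bm1$dW, b1 = bm1$db, W2 = bm2$dW, b2 = bm2$db))
}

#' Apply one shifted-window attention block
#'
#' @param tokens `n x C` token matrix, row-major over an `h x w` grid.
#' @param h,w token-grid shape.
#' @param params block parameters (see `init_sw_block`).
#' @param M window side length.
#' @param n_heads attention heads (C must be divisible).
#' @param shift logical: cyclic-shift the window grid by floor(M/2)?
#' @return refined `n x C` token matrix.
#' @export
sw_msa_block <- function(tokens, h, w, params, M, n_heads, shift = FALSE) {
  sw_block_fwd(tokens, h, w, params, M, n_heads, shift)$out
}

## ======================================================================
## Global encoder
## ======================================================================

init_global_encoder <- function(preset, in_ch = 1L) {
  p <- preset$patch
  C <- preset$global_channels
  M <- preset$window
  stages <- vector("list", length(C))
  for (s in seq_along(C)) {
    blocks <- lapply(seq_len(preset$global_depths[s]),
                     function(i) init_sw_block(C[s], M, preset$global_heads[s]))
    merge <- if (s > 1) {
      list(ln_g = rep(1, 4L * C[s - 1]), ln_b = rep(0, 4L * C[s - 1]),
           W = init_mat(4L * C[s - 1], C[s]))
    } else NULL
    stages[[s]] <- list(blocks = blocks, merge = merge)
  }
  list(embed = list(W = init_mat(p * p * in_ch, C[1]), b = rep(0, C[1]),
                    ln_g = rep(1, C[1]), ln_b = rep(0, C[1])),
       stages = stages)
}

global_encode_fwd <- function(image, params, preset) {
  H <- nrow(image); W <- ncol(image)
  stride <- preset_stride(preset)
  if (H %% stride != 0 || W %% stride != 0)
    stop("input size not divisible by total stride ", stride)
  M <- preset$window
  x <- array(image, c(H, W, 1L))
  tok <- patchify(x, preset$patch)
  em <- linear_fwd(tok, params$embed$W, params$embed$b)
  eln <- ln_fwd(em$out, params$embed$ln_g, params$embed$ln_b)
  h <- H %/% preset$patch; w <- W %/% preset$patch
  tokens <- eln$out
  caches <- list(embed = em$cache, embed_ln = eln$cache)
  stage_caches <- vector("list", length(params$stages))
  stage_tokens <- vector("list", length(params$stages))
  for (s in seq_along(params$stages)) {
    sc <- list()
    if (s > 1) {
      mg <- params$stages[[s]]$merge
      gr <- tokens_to_grid(tokens, h, w)
      mt <- patchify(gr, 2L)
      ml <- ln_fwd(mt, mg$ln_g, mg$ln_b)
      mo <- linear_fwd(ml$out, mg$W)
      h <- h %/% 2L; w <- w %/% 2L
      tokens <- mo$out
      sc$merge <- list(ln = ml$cache, lin = mo$cache, hw_in = c(h * 2L, w * 2L))
    }
    sc$blocks <- vector("list", length(params$stages[[s]]$blocks))
    for (b in seq_along(params$stages[[s]]$blocks)) {
      bf <- sw_block_fwd(tokens, h, w, params$stages[[s]]$blocks[[b]], M,
                         preset$global_heads[s], shift = (b %% 2L == 0L))
      tokens <- bf$out
      sc$blocks[[b]] <- bf$cache
    }
    stage_caches[[s]] <- sc
    stage_tokens[[s]] <- tokens
  }
  caches$stages <- stage_caches
  caches$final_hw <- c(h, w)
  list(out = tokens, h = h, w = w, cache = caches, stage_tokens = stage_tokens)
}

global_encode_bwd <- function(dout, cache, params, preset) {
  tokens_grad <- dout
  dstages <- vector("list", length(params$stages))
  hw <- cache$final_hw
  h <- hw[1]; w <- hw[2]
  for (s in rev(seq_along(params$stages))) {
    sc <- cache$stages[[s]]
    dblocks <- vector("list", length(sc$blocks))
    for (b in rev(seq_along(sc$blocks))) {
      bb <- sw_block_bwd(tokens_grad, sc$blocks[[b]], params$stages[[s]]$blocks[[b]])
      tokens_grad <- bb$dX
      dblocks[[b]] <- bb$dparams
    }
    dmerge <- NULL
    if (s > 1) {
      hw_in <- sc$merge$hw_in
      bl <- linear_bwd(tokens_grad, sc$merge$lin)
      bln <- ln_bwd(bl$dX, sc$merge$ln)
      dgr <- unpatchify(bln$dX, hw_in[1], hw_in[2],
                        length(params$stages[[s]]$merge$ln_g) %/% 4L, 2L)
      tokens_grad <- grid_to_tokens(dgr)
      h <- hw_in[1]; w <- hw_in[2]
      dmerge <- list(ln_g = bln$dgamma, ln_b = bln$dbeta, W = bl$dW)
    }
    dstages[[s]] <- list(blocks = dblocks, merge = dmerge)
  }
  beln <- ln_bwd(tokens_grad, cache$embed_ln)
  bem <- linear_bwd(beln$dX, cache$embed)
  list(dparams = list(embed = list(W = bem$dW, b = bem$db,
                                   ln_g = beln$dgamma, ln_b = beln$dbeta),
                      stages = dstages))
}

#' Encode an image with the global-context stream
#'
#' Patch embedding, hierarchical stages of shifted-window cosine-attention
#' blocks (alternating unshifted/shifted) with 2x patch merging between
#' stages; returns the final-stage token grid.
#'
#' @inheritParams local_encode
#' @param params parameters from [init_backbones()]`$global`.
#' @return list with `tokens` (`n x C` matrix), `h`, `w`, and per-stage
#'   token matrices in `stage_tokens`.
#' @export
global_encode <- function(image, params, preset) {
  f <- global_encode_fwd(image, params, preset)
  list(tokens = f$out, h = f$h, w = f$w, stage_tokens = f$stage_tokens)
}

#' Initialize both encoder streams
#'
#' @param preset a [backbone_preset()].
#' @param seed optional seed for reproducible initialization.
#' @return list with `local` and `global` parameter trees.
#' @export
init_backbones <- function(preset, seed = NULL) {
  with_seed(seed, list(local = init_local_encoder(preset),
                       global = init_global_encoder(preset)))
}
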