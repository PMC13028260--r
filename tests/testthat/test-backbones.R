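toy_preset <- function() {
  list(name = "toy", input_size = 48L, patch = 6L,
       local_channels = c(6L), local_depths = c(1L), dw_kernel = 5L,
       global_channels = c(6L), global_depths = c(1L),
       window = 4L, global_heads = c(2L),
       fusion_heads = 2L, fusion_d_head = 4L)
}

test_that("a zero input with zero shifts passes through the local block as zero", {
  set.seed(61)
  p <- mammofuse:::init_convnext_block(4L, 5L)
  x <- array(0, c(6, 6, 4))
  expect_equal(convnext_block(x, p), x)
})

test_that("the inverted bottleneck expands channels by 4 and restores them", {
  set.seed(62)
  C <- 5L
  p <- mammofuse:::init_convnext_block(C, 5L)
  expect_identical(dim(p$W1), c(C, 4L * C))
  expect_identical(dim(p$W2), c(4L * C, C))
  x <- array(rnorm(8 * 8 * C), c(8, 8, C))
  expect_identical(dim(convnext_block(x, p)), dim(x))
  expect_error(convnext_block(array(0, c(8, 8, C + 1L)), p), "channel mismatch")
})

test_that("a delta kernel with identity pointwise maps doubles the input", {
  C <- 3L; k <- 5L
  p <- list(dw = array(0, c(k, k, C)), dwb = rep(0, C),
            ln_g = rep(1, C), ln_b = rep(0, C),
            W1 = cbind(diag(C), matrix(0, C, 3 * C)), b1 = rep(0, 4 * C),
            W2 = rbind(diag(C), matrix(0, 3 * C, C)), b2 = rep(0, C))
  p$dw[(k + 1) / 2, (k + 1) / 2, ] <- 1          # centered delta per channel
  set.seed(63)
  x <- array(rnorm(7 * 7 * C), c(7, 7, C))
  out <- convnext_block(x, p, use_ln = FALSE, act = "identity")
  expect_equal(out, 2 * x, tolerance = 1e-12)
})

test_that("the local encoder produces the preset channel width and stride", {
  pr <- backbone_preset("tiny")
  params <- with_seed(64, mammofuse:::init_local_encoder(pr))
  img <- rand_img(96)
  f <- local_encode(img, params, pr)
  stride <- as.integer(pr$patch * 2^(length(pr$local_channels) - 1))
  expect_identical(dim(f), c(96L %/% stride, 96L %/% stride, 32L))
  expect_identical(attr(f, "stride"), stride)
  f2 <- local_encode(img, params, pr)
  expect_identical(unclass(f), unclass(f2))      # pure function of (weights, input)
  expect_error(local_encode(rand_img(50), params, pr), "divisible")
})

test_that("the base presets carry the reference dimensions end to end", {
  pr <- backbone_preset("base")
  expect_identical(pr$input_size, 384L)
  expect_identical(pr$window, 7L)
  expect_identical(pr$fusion_heads, 8L)
  expect_identical(pr$fusion_d_head, 128L)
  params <- with_seed(65, mammofuse:::init_local_encoder(pr))
  f <- local_encode(rand_img(384), params, pr)
  expect_identical(dim(f)[3], 1024L)             # stage-4 channel width
})

test_that("window partition and reverse are exact inverses, also under shifts", {
  set.seed(66)
  tokens <- matrix(rnorm(14 * 14 * 3), 14 * 14, 3)
  wins <- window_partition(tokens, 14, 14, 7)
  expect_length(wins, 4)
  expect_identical(dim(wins[[1]]), c(49L, 3L))
  expect_identical(window_reverse(wins, 14, 14, 7), tokens)
  rolled <- mammofuse:::roll_tokens(tokens, 14, 14, 3)
  back <- mammofuse:::roll_tokens(
    window_reverse(window_partition(rolled, 14, 14, 7), 14, 14, 7), 14, 14, -3)
  expect_identical(back, tokens)
})

test_that("scaled cosine attention normalizes rows and averages identical keys", {
  set.seed(67)
  Q <- matrix(rnorm(12), 4, 3)
  K <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)   # all keys identical
  V <- matrix(rnorm(10), 5, 2)
  a <- scaled_cosine_attention(Q, K, V, tau = 0.5)
  expect_equal(rowSums(a$weights), rep(1, 4))
  for (i in 1:4) expect_equal(a$out[i, ], colMeans(V))
  # distinct keys: rows still normalize, weights nonnegative
  K2 <- matrix(rnorm(15), 5, 3)
  a2 <- scaled_cosine_attention(Q, K2, V, tau = 0.2)
  expect_equal(rowSums(a2$weights), rep(1, 4))
  expect_true(all(a2$weights >= 0))
})

test_that("small temperature drives attention to the argmax-cosine key", {
  set.seed(68)
  Q <- matrix(rnorm(3), 1, 3)
  K <- matrix(rnorm(18), 6, 3)
  V <- matrix(rnorm(12), 6, 2)
  cosines <- as.vector((Q / sqrt(sum(Q^2))) %*% t(K / sqrt(rowSums(K^2))))
  stopifnot(diff(sort(cosines, decreasing = TRUE))[1] < -0.05)
  a <- scaled_cosine_attention(Q, K, V, tau = 1e-3)
  expect_equal(a$out[1, ], V[which.max(cosines), ], tolerance = 1e-2)
})

test_that("zero-norm queries are guarded to cosine zero", {
  Q <- rbind(c(0, 0), c(1, 0))
  K <- rbind(c(1, 0), c(0, 1))
  V <- diag(2)
  a <- scaled_cosine_attention(Q, K, V, tau = 1)
  expect_true(all(is.finite(a$out)))
  expect_equal(a$weights[1, ], c(0.5, 0.5))      # zero cosine to both keys
})

test_that("a zero value projection reduces the attention block to its MLP path", {
  set.seed(69)
  C <- 6L; M <- 4L
  p <- mammofuse:::init_sw_block(C, M, 2L)
  p$Wqkv[, (2 * C + 1):(3 * C)] <- 0             # zero the value projection
  p$bqkv[(2 * C + 1):(3 * C)] <- 0
  tokens <- matrix(rnorm(64 * C), 64, C)
  out <- sw_msa_block(tokens, 8, 8, p, M, 2L, shift = FALSE)
  n1 <- mammofuse:::ln_fwd(tokens, p$ln1_g, p$ln1_b)$out
  mlp <- mammofuse:::linear_fwd(
    mammofuse:::gelu_fwd(mammofuse:::linear_fwd(n1, p$W1, p$b1)$out)$out,
    p$W2, p$b2)$out
  expected <- mammofuse:::ln_fwd(n1 + mlp, p$ln2_g, p$ln2_b)$out
  expect_equal(out, expected, tolerance = 1e-12)
})

test_that("unshifted windows never attend across window boundaries", {
  set.seed(70)
  C <- 4L; M <- 4L
  p <- mammofuse:::init_sw_block(C, M, 2L)
  tokens <- matrix(rnorm(32 * C), 32, C)         # 4 x 8 grid, two windows
  base <- sw_msa_block(tokens, 4, 8, p, M, 2L, shift = FALSE)
  w2_cols <- as.vector(mammofuse:::win_index(4, 8, 4)[2, ])
  tokens2 <- tokens
  tokens2[w2_cols, ] <- tokens2[w2_cols, ] + rnorm(length(w2_cols) * C)
  pert <- sw_msa_block(tokens2, 4, 8, p, M, 2L, shift = FALSE)
  w1_cols <- as.vector(mammofuse:::win_index(4, 8, 4)[1, ])
  expect_equal(pert[w1_cols, ], base[w1_cols, ], tolerance = 1e-12)
})

test_that("masked shifted attention equals per-neighborhood attention", {
  set.seed(71)
  C <- 4L; M <- 4L; h <- 4L; w <- 8L; shift <- 2L
  p <- mammofuse:::init_sw_block(C, M, 1L)
  p$bias_table[] <- 0
  p$tau <- 0.7
  p$Wp <- diag(C); p$bp <- rep(0, C)
  p$W1[] <- 0; p$b1[] <- 0; p$W2[] <- 0; p$b2 <- rep(0, C)  # silence the MLP
  tokens <- matrix(rnorm(h * w * C), h * w, C)
  got <- sw_msa_block(tokens, h, w, p, M, 1L, shift = TRUE)

  # independent neighborhood oracle: a token's group is (shifted window id,
  # region id); attention runs over its group only
  qkv <- sweep(tokens %*% p$Wqkv, 2, p$bqkv, "+")
  q <- qkv[, 1:C]; k <- qkv[, C + 1:C]; v <- qkv[, 2 * C + 1:C]
  pos <- cbind(rep(seq_len(h), each = w), rep(seq_len(w), times = h))  # row-major
  seg <- function(i, n) ifelse(i <= n - M, 0L, ifelse(i <= n - shift, 1L, 2L))
  region <- seg(pos[, 1], h) * 3L + seg(pos[, 2], w)
  swin <- function(i, n) ((i - 1 - shift) %% n) %/% M   # window band after roll
  wid <- swin(pos[, 1], h) * 10L + swin(pos[, 2], w)
  group <- paste(region, wid)
  oracle_attn <- matrix(0, h * w, C)
  for (g in unique(group)) {
    idx <- which(group == g)
    qh <- q[idx, , drop = FALSE] / sqrt(rowSums(q[idx, , drop = FALSE]^2))
    kh <- k[idx, , drop = FALSE] / sqrt(rowSums(k[idx, , drop = FALSE]^2))
    S <- (qh %*% t(kh)) / 0.7
    P <- t(apply(S, 1, soft))
    if (length(idx) == 1) P <- matrix(1, 1, 1)
    oracle_attn[idx, ] <- P %*% v[idx, , drop = FALSE]
  }
  n1 <- mammofuse:::ln_fwd(tokens + oracle_attn, p$ln1_g, p$ln1_b)$out
  expected <- mammofuse:::ln_fwd(n1, p$ln2_g, p$ln2_b)$out
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("the global encoder is deterministic with the expected token count", {
  pr <- backbone_preset("tiny")
  params <- with_seed(72, mammofuse:::init_global_encoder(pr))
  img <- rand_img(96)
  g1 <- global_encode(img, params, pr)
  g2 <- global_encode(img, params, pr)
  expect_identical(g1$tokens, g2$tokens)
  expect_true(all(is.finite(g1$tokens)))
  stride <- as.integer(pr$patch * 2^(length(pr$global_channels) - 1))
  expect_identical(nrow(g1$tokens), (96L %/% stride) * (96L %/% stride))
  expect_identical(ncol(g1$tokens), 32L)
})

test_that("unshifted window stages are equivariant to whole-window image shifts", {
  pr <- toy_preset()
  params <- with_seed(73, mammofuse:::init_global_encoder(pr))
  # periodic image, period = one window of patches = window * patch pixels
  period <- pr$window * pr$patch                 # 24 px
  base <- matrix(rep(rand_img(period, 48), length.out = 48 * 48), 48, 48)
  shifted <- base[c((period + 1):48, 1:period), ]    # cyclic shift by one period
  t_base <- global_encode(base, params, pr)$tokens
  t_shift <- global_encode(shifted, params, pr)$tokens
  gh <- 48L %/% pr$patch                          # 8 x 8 token grid
  # row-major tokens: index (r, c) -> (r-1)*gh + c
  idx <- function(r, c) (r - 1L) * gh + c
  for (r in 1:gh) for (c in 1:gh) {
    r_src <- ((r - 1L + pr$window) %% gh) + 1L   # shifted image row r = base row r+M
    expect_equal(t_shift[idx(r, c), ], t_base[idx(r_src, c), ], tolerance = 1e-10)
  }
})

test_that("the tiny forward pass is fast enough for interactive use", {
  m <- build_model("tiny", "full", seed = 74)
  img <- rand_img(96)
  invisible(model_forward(m, img))               # warm the index caches
  t <- system.time(model_forward(m, img))["elapsed"]
  expect_lt(t, 1)
})
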