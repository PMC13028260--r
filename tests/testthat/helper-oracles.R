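# shared helpers for building small random inputs and independent oracles

rand_img <- function(h, w = h, lo = 0, hi = 1) {
  matrix(stats::runif(h * w, lo, hi), h, w)
}

# independent global histogram equalization: quantize to 256 bins over the
# image range, map each pixel to its empirical CDF value rescaled to the
# original range
global_hist_eq_oracle <- function(x, n_bins = 256L) {
  lo <- min(x); hi <- max(x)
  b <- pmin(pmax(floor((x - lo) / (hi - lo) * n_bins) + 1L, 1L), n_bins)
  cdf <- stats::ecdf(b)
  matrix(lo + (hi - lo) * cdf(b), nrow(x), ncol(x))
}

# direct per-pixel bilinear resize oracle (pixel centers at half-integers)
bilinear_oracle <- function(img, oh, ow) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, oh, ow)
  for (i in seq_len(oh)) for (j in seq_len(ow)) {
    sr <- (i - 0.5) * H / oh + 0.5
    sc <- (j - 0.5) * W / ow + 0.5
    r0 <- min(max(floor(sr), 1), H); r1 <- min(r0 + 1, H)
    c0 <- min(max(floor(sc), 1), W); c1 <- min(c0 + 1, W)
    wr <- min(max(sr - r0, 0), 1); wc <- min(max(sc - c0, 0), 1)
    out[i, j] <- (1 - wr) * (1 - wc) * img[r0, c0] + wr * (1 - wc) * img[r1, c0] +
      (1 - wr) * wc * img[r0, c1] + wr * wc * img[r1, c1]
  }
  out
}

# reference softmax for small oracles
soft <- function(v) exp(v - max(v)) / sum(exp(v - max(v)))
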