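#' Image conditioning and online augmentation
#'
#' Deterministic conditioning (CLAHE, min-max normalization, bilinear resize)
#' runs on every image; stochastic augmentation (geometric policy,
#' RandAugment-style operations, MixUp) is applied to training images only.
#' Images are plain numeric matrices, rows = image height, and after
#' normalization every value lies in [0, 1].
#'
#' @name preprocess
NULL

N_HIST_BINS <- 256L

quantize_bins <- function(x, lo, hi, n_bins = N_HIST_BINS) {
  b <- floor((x - lo) / (hi - lo) * n_bins) + 1L
  pmin(pmax(b, 1L), n_bins)
}

#' Clip a histogram and redistribute the excess uniformly
#'
#' The clip ceiling is `clip_limit` times the uniform bin height
#' (pixel count / number of bins). Mass above the ceiling is removed and
#' spread evenly over all bins, so total mass is conserved.
#'
#' @param h integer vector of histogram counts.
#' @param clip_limit positive multiple of the uniform bin height.
#' @return numeric vector of adjusted counts, same sum as `h`.
#' @export
clip_histogram <- function(h, clip_limit) {
  stopifnot(clip_limit > 0)
  n <- sum(h)
  ceiling_count <- clip_limit * n / length(h)
  excess <- sum(pmax(h - ceiling_count, 0))
  pmin(h, ceiling_count) + excess / length(h)
}

#' Contrast Limited Adaptive Histogram Equalization
#'
#' Per-tile histogram equalization with the tile histogram clipped at
#' `clip_limit` times the uniform bin height and the excess redistributed
#' uniformly before the cumulative mapping is formed. Per-pixel output is the
#' bilinear blend of the four surrounding tile mappings (standard CLAHE
#' inter-tile interpolation). A zero-dynamic-range image passes through
#' unchanged. Intensities keep their original range: the mapping sends the
#' clipped CDF into [min(x), max(x)].
#'
#' @param image numeric matrix of finite intensities.
#' @param clip_limit positive clip factor relative to the uniform bin height
#'   (default 2.0).
#' @param tile_grid integer pair, tiles along (rows, cols); default `c(8, 8)`.
#' @return matrix of the same shape.
#' @export
apply_clahe <- function(image, clip_limit = 2.0, tile_grid = c(8L, 8L)) {
  stopifnot(is.matrix(image), nrow(image) >= 1, ncol(image) >= 1)
  stopifnot_finite(image, "image")
  stopifnot(clip_limit > 0, length(tile_grid) == 2, all(tile_grid >= 1))
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(image)  # degenerate histogram: identity

  ty <- as.integer(tile_grid[1]); tx <- as.integer(tile_grid[2])
  H <- nrow(image); W <- ncol(image)
  # pad by edge replication so tiles divide the extent
  th <- ceiling(H / ty); tw <- ceiling(W / tx)
  Hp <- th * ty; Wp <- tw * tx
  ridx <- pmin(seq_len(Hp), H); cidx <- pmin(seq_len(Wp), W)
  padded <- image[ridx, cidx, drop = FALSE]
  bins_pad <- matrix(quantize_bins(padded, lo, hi), Hp, Wp)

  # per-tile clipped-CDF mappings: maps[bin, tile_row, tile_col] in [lo, hi]
  maps <- array(0, dim = c(N_HIST_BINS, ty, tx))
  for (tr in seq_len(ty)) {
    for (tc in seq_len(tx)) {
      tile <- bins_pad[((tr - 1) * th + 1):(tr * th), ((tc - 1) * tw + 1):(tc * tw)]
      h <- tabulate(tile, nbins = N_HIST_BINS)
      h <- clip_histogram(h, clip_limit)
      cdf <- cumsum(h) / sum(h)
      maps[, tr, tc] <- lo + (hi - lo) * cdf
    }
  }

  # bilinear blend of tile mappings at each original pixel
  interp_axis <- function(n_pix, tile_len, n_tiles) {
    g <- (seq_len(n_pix) - 0.5) / tile_len + 0.5
    f <- floor(g)
    t0 <- pmin(pmax(f, 1), n_tiles)
    t1 <- pmin(t0 + 1, n_tiles)
    w <- ifelse(f < 1 | f >= n_tiles, 0, g - f)  # clamp outside tile centers
    list(t0 = t0, t1 = t1, w = w)
  }
  ra <- interp_axis(H, th, ty)
  ca <- interp_axis(W, tw, tx)
  bins <- bins_pad[seq_len(H), seq_len(W), drop = FALSE]
  bv <- as.vector(bins)
  r0 <- rep(ra$t0, times = W); r1 <- rep(ra$t1, times = W); wr <- rep(ra$w, times = W)
  c0 <- rep(ca$t0, each = H); c1 <- rep(ca$t1, each = H); wc <- rep(ca$w, each = H)
  out <- (1 - wr) * (1 - wc) * maps[cbind(bv, r0, c0)] +
         wr      * (1 - wc) * maps[cbind(bv, r1, c0)] +
         (1 - wr) * wc      * maps[cbind(bv, r0, c1)] +
         wr      * wc      * maps[cbind(bv, r1, c1)]
  matrix(out, H, W)
}

#' Min-max normalization to [0, 1]
#'
#' Affine map `(x - min) / (max - min)`. A constant image maps to all zeros
#' (with a warning): the division guard keeps the output deterministic and
#' inside the unit interval.
#'
#' @param image numeric matrix of finite intensities.
#' @return matrix with values in [0, 1].
#' @export
minmax_normalize <- function(image) {
  stopifnot(is.matrix(image), length(image) >= 1)
  stopifnot_finite(image, "image")
  lo <- min(image); hi <- max(image)
  if (hi == lo) {
    warning("constant image: min-max normalization returns all zeros")
    return(matrix(0, nrow(image), ncol(image)))
  }
  (image - lo) / (hi - lo)
}

#' Bilinear resize
#'
#' Pixel centers sit at half-integer offsets (align-corners-false), so
#' resizing to the same size is the identity and a constant image stays
#' constant. Values are clipped to [0, 1] afterwards.
#'
#' @param image numeric matrix with values in [0, 1].
#' @param target_size integer length-1 or length-2 (rows, cols).
#' @return matrix of the target shape.
#' @export
resize_to_input <- function(image, target_size = 384L) {
  stopifnot(is.matrix(image), all(target_size >= 1))
  if (length(target_size) == 1) target_size <- c(target_size, target_size)
  H <- nrow(image); W <- ncol(image)
  oh <- as.integer(target_size[1]); ow <- as.integer(target_size[2])
  if (oh == H && ow == W) return(image)
  axis_coords <- function(n_out, n_in) {
    src <- (seq_len(n_out) - 0.5) * (n_in / n_out) + 0.5
    i0 <- pmin(pmax(floor(src), 1), n_in)
    i1 <- pmin(i0 + 1, n_in)
    w <- pmin(pmax(src - i0, 0), 1)
    list(i0 = i0, i1 = i1, w = w)
  }
  ry <- axis_coords(oh, H); rx <- axis_coords(ow, W)
  top    <- image[ry$i0, , drop = FALSE]
  bottom <- image[ry$i1, , drop = FALSE]
  rows   <- top * (1 - ry$w) + bottom * ry$w
  left   <- rows[, rx$i0, drop = FALSE]
  right  <- rows[, rx$i1, drop = FALSE]
  out <- left * matrix(1 - rx$w, oh, ow, byrow = TRUE) +
         right * matrix(rx$w, oh, ow, byrow = TRUE)
  clip01(out)
}

# reflect a continuous coordinate into [1, n] (mirror about pixel centers)
reflect_coord <- function(x, n) {
  if (n == 1) return(rep(1, length(x)))
  period <- 2 * (n - 1)
  x <- (x - 1) %% period
  ifelse(x > (n - 1), period - x, x) + 1
}

# sample image at continuous (row, col) coordinates with bilinear
# interpolation and reflection padding
sample_bilinear <- function(image, rr, cc) {
  H <- nrow(image); W <- ncol(image)
  rr <- reflect_coord(rr, H); cc <- reflect_coord(cc, W)
  r0 <- pmin(pmax(floor(rr), 1), H); r1 <- pmin(r0 + 1, H)
  c0 <- pmin(pmax(floor(cc), 1), W); c1 <- pmin(c0 + 1, W)
  wr <- rr - r0; wc <- cc - c0
  v <- (1 - wr) * (1 - wc) * image[cbind(r0, c0)] +
       wr      * (1 - wc) * image[cbind(r1, c0)] +
       (1 - wr) * wc      * image[cbind(r0, c1)] +
       wr      * wc      * image[cbind(r1, c1)]
  matrix(v, H, W)
}

#' Affine warp of an image about its center
#'
#' Inverse-mapped bilinear resampling with reflection padding. Rotation in
#' degrees, translation in pixels, shear as slope factors, optional
#' horizontal flip.
#' @noRd
affine_warp <- function(image, rot_deg = 0, tx = 0, ty = 0,
                        shear_x = 0, shear_y = 0, hflip = FALSE) {
  H <- nrow(image); W <- ncol(image)
  if (rot_deg == 0 && tx == 0 && ty == 0 && shear_x == 0 && shear_y == 0 && !hflip) {
    return(image)
  }
  th <- rot_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  S <- matrix(c(1, shear_x, shear_y, 1), 2, 2, byrow = TRUE)
  Fm <- if (hflip) matrix(c(1, 0, 0, -1), 2, 2, byrow = TRUE) else diag(2)
  A <- R %*% S %*% Fm                      # forward map (row, col) offsets
  Ainv <- solve(A)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  og <- expand.grid(r = seq_len(H), c = seq_len(W))
  dy <- og$r - cy - ty
  dx <- og$c - cx - tx
  src_r <- Ainv[1, 1] * dy + Ainv[1, 2] * dx + cy
  src_c <- Ainv[2, 1] * dy + Ainv[2, 2] * dx + cx
  sample_bilinear(image, src_r, src_c)
}

#' Construct an augmentation policy
#'
#' Bundles the stochastic-augmentation parameters: the RandAugment-style
#' operation count and magnitude, the geometric limits, and the horizontal
#' flip probability. Defaults follow the training recipe: 2 operations at
#' magnitude 9, rotations within +/-10 degrees, horizontal flip.
#'
#' @param n_ops number of RandAugment operations sampled per image.
#' @param magnitude shared integer magnitude in [0, 30].
#' @param rotation_limit_deg rotation limit (degrees, >= 0).
#' @param hflip_prob horizontal flip probability.
#' @param translate_frac translation limit as a fraction of image size.
#' @param shear_deg shear limit in degrees.
#' @return an object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(n_ops = 2L, magnitude = 9L,
                                rotation_limit_deg = 10, hflip_prob = 0.5,
                                translate_frac = 0.05, shear_deg = 5) {
  stopifnot(n_ops >= 0, magnitude >= 0, magnitude <= 30,
            rotation_limit_deg >= 0, hflip_prob >= 0, hflip_prob <= 1,
            translate_frac >= 0, translate_frac <= 0.5,
            shear_deg >= 0, shear_deg <= 45)
  structure(list(n_ops = as.integer(n_ops), magnitude = as.integer(magnitude),
                 rotation_limit_deg = rotation_limit_deg,
                 hflip_prob = hflip_prob, translate_frac = translate_frac,
                 shear_deg = shear_deg),
            class = "augmentation_policy")
}

#' One stochastic geometric augmentation draw
#'
#' Composes a rotation within the policy limit, bounded translation and
#' shear, and an optional horizontal flip, with reflection padding at the
#' borders. Magnitudes are bounded by the (validated) policy so lesion-scale
#' morphology is preserved. Consumes the current RNG stream.
#'
#' @param image preprocessed image matrix in [0, 1].
#' @param policy an [augmentation_policy()].
#' @return augmented image matrix, same shape.
#' @export
random_geometric_augment <- function(image, policy = augmentation_policy()) {
  stopifnot(inherits(policy, "augmentation_policy"))
  rot <- if (policy$rotation_limit_deg > 0)
    stats::runif(1, -policy$rotation_limit_deg, policy$rotation_limit_deg) else 0
  tmax_x <- policy$translate_frac * ncol(image)
  tmax_y <- policy$translate_frac * nrow(image)
  tx <- if (tmax_x > 0) stats::runif(1, -tmax_x, tmax_x) else 0
  ty <- if (tmax_y > 0) stats::runif(1, -tmax_y, tmax_y) else 0
  smax <- tan(policy$shear_deg * pi / 180)
  sx <- if (smax > 0) stats::runif(1, -smax, smax) else 0
  sy <- if (smax > 0) stats::runif(1, -smax, smax) else 0
  flip <- policy$hflip_prob > 0 && stats::runif(1) < policy$hflip_prob
  clip01(affine_warp(image, rot, tx, ty, sx, sy, flip))
}

# grayscale-safe RandAugment operation pool; each op takes (image, signed
# strength s in [-1, 1] scaled by magnitude/30)
blur3 <- function(x) {
  k <- c(0.25, 0.5, 0.25)
  H <- nrow(x); W <- ncol(x)
  pad_r <- x[c(1, seq_len(H), H), , drop = FALSE]
  xr <- k[1] * pad_r[seq_len(H), ] + k[2] * pad_r[seq_len(H) + 1, ] +
        k[3] * pad_r[seq_len(H) + 2, ]
  pad_c <- xr[, c(1, seq_len(W), W), drop = FALSE]
  k[1] * pad_c[, seq_len(W)] + k[2] * pad_c[, seq_len(W) + 1] +
    k[3] * pad_c[, seq_len(W) + 2]
}

equalize_global <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(x)
  b <- quantize_bins(x, lo, hi)
  cdf <- cumsum(tabulate(b, nbins = N_HIST_BINS)) / length(x)
  matrix(lo + (hi - lo) * cdf[b], nrow(x), ncol(x))
}

rand_augment_ops <- function() {
  list(
    identity    = function(x, s) x,
    rotate      = function(x, s) affine_warp(x, rot_deg = s * 30),
    translate_x = function(x, s) affine_warp(x, tx = s * 0.2 * ncol(x)),
    translate_y = function(x, s) affine_warp(x, ty = s * 0.2 * nrow(x)),
    shear_x     = function(x, s) affine_warp(x, shear_x = s * 0.3),
    shear_y     = function(x, s) affine_warp(x, shear_y = s * 0.3),
    contrast    = function(x, s) mean(x) + (1 + s * 0.9) * (x - mean(x)),
    brightness  = function(x, s) x + s * 0.3,
    sharpness   = function(x, s) x + s * 1.5 * (x - blur3(x)),
    autocontrast = function(x, s) if (max(x) > min(x)) (x - min(x)) / (max(x) - min(x)) else x,
    equalize    = function(x, s) equalize_global(x)
  )
}

#' RandAugment-style augmentation
#'
#' Samples `n_ops` operations uniformly with replacement from a
#' grayscale-safe, morphology-preserving pool (rotate, translate, shear,
#' contrast, brightness, sharpness, autocontrast, equalize, identity) and
#' applies each at the shared `magnitude` (0-30 scale) with a random sign.
#' Output is clipped to [0, 1]. Consumes the current RNG stream.
#'
#' @param image matrix in [0, 1].
#' @param n_ops number of operations (default 2).
#' @param magnitude shared magnitude level in [0, 30] (default 9).
#' @param op_pool optional named list of operations `(image, s) -> image`.
#' @return augmented matrix in [0, 1].
#' @export
rand_augment <- function(image, n_ops = 2L, magnitude = 9L,
                         op_pool = rand_augment_ops()) {
  stopifnot(n_ops >= 0, magnitude >= 0, magnitude <= 30)
  if (length(op_pool) == 0) stop("rand_augment: empty operation pool")
  if (n_ops == 0) return(image)
  picks <- sample.int(length(op_pool), n_ops, replace = TRUE)
  for (p in picks) {
    s <- (magnitude / 30) * sample(c(-1, 1), 1)
    image <- clip01(op_pool[[p]](image, s))
  }
  image
}

#' MixUp batch augmentation
#'
#' Pairs each sample with a random permutation partner and forms convex
#' combinations `lambda * x_i + (1 - lambda) * x_j` of both images and
#' one-hot labels, with `lambda ~ Beta(alpha, alpha)` drawn per pair. The
#' same lambda mixes an image and its label. A batch of one passes through
#' with lambda = 1 and a warning.
#'
#' @param images list of image matrices (equal shapes).
#' @param labels n x K matrix of (possibly already soft) label vectors.
#' @param alpha positive Beta concentration (default 0.3).
#' @param lambda optional fixed mixing coefficient(s) overriding the Beta
#'   draw (recycled to the batch size); mainly for deterministic checks.
#' @return list with `images`, `soft_labels`, `lambdas`, `pairing`.
#' @export
mixup <- function(images, labels, alpha = 0.3, lambda = NULL) {
  stopifnot(alpha > 0, is.matrix(labels), length(images) == nrow(labels))
  n <- length(images)
  if (n < 2) {
    warning("mixup: batch of size 1, passing through with lambda = 1")
    return(list(images = images, soft_labels = labels,
                lambdas = rep(1, n), pairing = seq_len(n)))
  }
  perm <- sample.int(n)
  lam <- if (is.null(lambda)) stats::rbeta(n, alpha, alpha)
         else rep_len(lambda, n)
  mixed <- vector("list", n)
  soft <- matrix(0, n, ncol(labels))
  for (i in seq_len(n)) {
    j <- perm[i]
    mixed[[i]] <- lam[i] * images[[i]] + (1 - lam[i]) * images[[j]]
    soft[i, ] <- lam[i] * labels[i, ] + (1 - lam[i]) * labels[j, ]
  }
  list(images = mixed, soft_labels = soft, lambdas = lam, pairing = perm)
}

#' Full preprocessing pipeline for one image
#'
#' CLAHE, min-max normalization and bilinear resize always run; the
#' stochastic geometric and RandAugment policies run only when
#' `train_mode = TRUE` (MixUp is a batch-level step, see [mixup()]).
#' With `train_mode = FALSE` the output is a deterministic function of the
#' input and no RNG is consumed.
#'
#' @param raw numeric matrix of finite nonnegative intensities.
#' @param train_mode logical; apply stochastic augmentation?
#' @param policy an [augmentation_policy()].
#' @param target_size output side length (default 384).
#' @param clip_limit CLAHE clip factor (default 2.0); `NULL` skips CLAHE.
#' @param tile_grid CLAHE tile grid (default 8 x 8).
#' @return matrix `target_size x target_size` in [0, 1], with a `provenance`
#'   attribute listing applied steps.
#' @export
preprocess_pipeline <- function(raw, train_mode = FALSE,
                                policy = augmentation_policy(),
                                target_size = 384L,
                                clip_limit = 2.0, tile_grid = c(8L, 8L)) {
  steps <- character(0)
  x <- raw
  if (!is.null(clip_limit)) {
    x <- apply_clahe(x, clip_limit, tile_grid)
    steps <- c(steps, sprintf("clahe(clip=%.3g)", clip_limit))
  }
  x <- suppressWarnings(minmax_normalize(x))
  steps <- c(steps, "minmax")
  x <- resize_to_input(x, target_size)
  steps <- c(steps, sprintf("resize(%d)", as.integer(target_size[1])))
  if (isTRUE(train_mode)) {
    x <- random_geometric_augment(x, policy)
    x <- rand_augment(x, policy$n_ops, policy$magnitude)
    steps <- c(steps, "geometric", sprintf("randaugment(n=%d,m=%d)",
                                           policy$n_ops, policy$magnitude))
  }
  attr(x, "provenance") <- steps
  x
}
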