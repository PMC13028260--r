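test_that("CLAHE passes constant images through and rejects non-finite input", {
  img <- matrix(0.7, 20, 20)
  expect_identical(apply_clahe(img), img)
  bad <- img; bad[3, 3] <- NA
  expect_error(apply_clahe(bad), "non-finite")
})

test_that("single-tile CLAHE with a high clip equals global histogram equalization", {
  set.seed(41)
  img <- matrix(rgamma(32 * 32, shape = 2, rate = 1), 32, 32)
  got <- apply_clahe(img, clip_limit = 1e6, tile_grid = c(1, 1))
  expect_equal(got, global_hist_eq_oracle(img), tolerance = 1e-12)
})

test_that("clipped histograms conserve mass", {
  set.seed(42)
  for (i in 1:20) {
    h <- rpois(256, lambda = runif(1, 0.5, 20))
    cl <- runif(1, 0.5, 5)
    expect_equal(sum(clip_histogram(h, cl)), sum(h), tolerance = 1e-9)
    expect_true(all(clip_histogram(h, cl) <= cl * sum(h) / 256 + sum(h) / 256))
  }
})

test_that("CLAHE keeps shape and stays within the input range", {
  set.seed(43)
  img <- rand_img(37, 29, 0, 4)   # sides not divisible by the tile grid
  out <- apply_clahe(img, 2.0, c(4, 4))
  expect_identical(dim(out), dim(img))
  expect_true(all(out >= min(img) - 1e-12 & out <= max(img) + 1e-12))
})

test_that("min-max normalization maps range to [0,1] with a constant-image guard", {
  expect_equal(as.vector(minmax_normalize(matrix(c(2, 4, 6), 1))), c(0, 0.5, 1))
  expect_warning(z <- minmax_normalize(matrix(5, 3, 3)), "constant")
  expect_identical(z, matrix(0, 3, 3))
  img <- matrix(c(0, 0.25, 0.5, 1), 2)
  expect_identical(minmax_normalize(img), img)   # already spans [0,1]
})

test_that("bilinear resize is identity at equal size and exact for constants", {
  img <- rand_img(16)
  expect_identical(resize_to_input(img, 16L), img)
  expect_equal(resize_to_input(matrix(0.4, 5, 7), c(11L, 13L)),
               matrix(0.4, 11, 13))
})

test_that("bilinear resize matches a direct closed-form evaluation", {
  checker <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(resize_to_input(checker, 4L), bilinear_oracle(checker, 4, 4))
  set.seed(44)
  img <- rand_img(7, 5)
  expect_equal(resize_to_input(img, c(12L, 9L)), bilinear_oracle(img, 12, 9))
})

test_that("degenerate geometric policy is the identity", {
  pol <- augmentation_policy(rotation_limit_deg = 0, hflip_prob = 0,
                             translate_frac = 0, shear_deg = 0)
  img <- rand_img(24)
  set.seed(1)
  expect_identical(random_geometric_augment(img, pol), img)
})

test_that("horizontal flip is an involution", {
  pol <- augmentation_policy(rotation_limit_deg = 0, hflip_prob = 1,
                             translate_frac = 0, shear_deg = 0)
  img <- rand_img(20)
  set.seed(2)
  once <- random_geometric_augment(img, pol)
  twice <- random_geometric_augment(once, pol)
  expect_equal(twice, img, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(once, img)))
})

test_that("geometric augmentation is reproducible under a fixed seed", {
  pol <- augmentation_policy()
  img <- rand_img(24)
  set.seed(7); a <- random_geometric_augment(img, pol)
  set.seed(7); b <- random_geometric_augment(img, pol)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
})

test_that("policy validation rejects out-of-bound magnitudes", {
  expect_error(augmentation_policy(magnitude = 31))
  expect_error(augmentation_policy(rotation_limit_deg = -1))
  expect_error(augmentation_policy(hflip_prob = 1.5))
})

test_that("rand_augment respects degenerate configurations and stays in range", {
  img <- rand_img(20)
  expect_identical(rand_augment(img, n_ops = 0), img)
  set.seed(3)
  expect_identical(rand_augment(img, 5, 20, op_pool = list(identity = function(x, s) x)),
                   img)
  expect_error(rand_augment(img, 2, 9, op_pool = list()), "empty")
  set.seed(4); a <- rand_augment(img, 2, 9)
  set.seed(4); b <- rand_augment(img, 2, 9)
  expect_identical(a, b)
  set.seed(5)
  for (i in 1:10) {
    out <- rand_augment(rand_img(16), 2, 30)
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("mixup forms convex combinations with shared image/label lambda", {
  imgs <- list(matrix(0, 4, 4), matrix(1, 4, 4))
  labs <- rbind(c(1, 0), c(0, 1))
  # find a seed whose permutation pairs the two opposite-class images
  seed <- 1
  repeat {
    set.seed(seed)
    if (identical(sample.int(2), c(2L, 1L))) break
    seed <- seed + 1
  }
  set.seed(seed)
  mid <- mixup(imgs, labs, lambda = 0.5)
  expect_equal(mid$images[[1]], matrix(0.5, 4, 4))
  expect_equal(unname(mid$soft_labels[1, ]), c(0.5, 0.5))
  set.seed(seed)
  idp <- mixup(imgs, labs, lambda = 1)
  expect_identical(idp$images, imgs)
  expect_equal(idp$soft_labels, labs, ignore_attr = TRUE)
})

test_that("mixup conserves label mass and reproduces under a seed", {
  set.seed(8)
  imgs <- replicate(6, rand_img(8), simplify = FALSE)
  labs <- one_hot_test <- cbind(1 - rbinom(6, 1, 0.5), NA)
  labs[, 2] <- 1 - labs[, 1]
  set.seed(9); a <- mixup(imgs, labs, alpha = 0.3)
  set.seed(9); b <- mixup(imgs, labs, alpha = 0.3)
  expect_identical(a$lambdas, b$lambdas)
  expect_identical(a$pairing, b$pairing)
  expect_equal(rowSums(a$soft_labels), rep(1, 6))
  expect_warning(one <- mixup(imgs[1], labs[1, , drop = FALSE]), "size 1")
  expect_identical(one$lambdas, 1)
})

test_that("the evaluation path of the pipeline is deterministic and in range", {
  set.seed(10)
  img <- rand_img(30, 30, 0, 255)
  rng_before <- .Random.seed
  a <- preprocess_pipeline(img, train_mode = FALSE, target_size = 24L)
  expect_identical(.Random.seed, rng_before)   # no RNG consumed
  b <- preprocess_pipeline(img, train_mode = FALSE, target_size = 24L)
  expect_identical(a, b)
  expect_identical(dim(a), c(24L, 24L))
  expect_true(all(a >= 0 & a <= 1))
  expect_true("minmax" %in% attr(a, "provenance"))
})

test_that("training mode with a degenerate policy equals evaluation mode", {
  pol <- augmentation_policy(n_ops = 0, magnitude = 0, rotation_limit_deg = 0,
                             hflip_prob = 0, translate_frac = 0, shear_deg = 0)
  img <- rand_img(30, 30, 0, 12)
  set.seed(11)
  tr <- preprocess_pipeline(img, TRUE, pol, target_size = 24L)
  ev <- preprocess_pipeline(img, FALSE, pol, target_size = 24L)
  expect_equal(unclass(tr), unclass(ev), ignore_attr = TRUE)
})

test_that("pipeline output lies in [0,1] for arbitrary finite inputs", {
  set.seed(12)
  for (i in 1:8) {
    img <- rand_img(sample(10:40, 1), sample(10:40, 1),
                    lo = runif(1, -5, 0), hi = runif(1, 1, 1e4))
    out <- preprocess_pipeline(img, train_mode = TRUE, target_size = 24L)
    expect_true(all(out >= 0 & out <= 1))
  }
})
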