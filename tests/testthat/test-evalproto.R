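make_table <- function(n_patients, malignant_frac, seed, max_imgs = 3) {
  set.seed(seed)
  lab <- ifelse(runif(n_patients) < malignant_frac, "malignant", "benign")
  cnt <- sample(seq_len(max_imgs), n_patients, replace = TRUE)
  data.frame(patient_id = rep(sprintf("P%04d", seq_len(n_patients)), cnt),
             label = rep(lab, cnt), stringsAsFactors = FALSE)
}

test_that("patient-level split holds the requested patient fraction and never leaks", {
  tab <- make_table(10, 0.5, 1)
  sp <- patient_level_split(tab, 0.2, seed = 3)
  expect_identical(sum(sp$partition == "test"), 2L)
  dev_imgs <- tab$patient_id[tab$patient_id %in% sp$patient_id[sp$partition == "dev"]]
  test_imgs <- tab$patient_id[tab$patient_id %in% sp$patient_id[sp$partition == "test"]]
  expect_length(intersect(dev_imgs, test_imgs), 0)
  expect_error(patient_level_split(make_table(3, 0.01, 2), 0.2, 1), "at least 2")
})

test_that("split stratification tracks the cohort malignant fraction", {
  tab <- make_table(1000, 0.3, 4)
  sp <- patient_level_split(tab, 0.2, seed = 5)
  test_lab <- sp$label[sp$partition == "test"]
  frac <- mean(test_lab == "malignant")
  overall <- mean(sp$label == "malignant")
  expect_lt(abs(frac - overall), 0.02)
})

test_that("stratified k-fold partitions the development patients evenly", {
  tab <- make_table(500, 0.3, 6)
  fd <- stratified_kfold_patients(tab, k = 5, seed = 7)
  expect_setequal(fd$patient_id, unique(tab$patient_id))
  expect_identical(anyDuplicated(fd$patient_id), 0L)
  sizes <- table(fd$fold)
  expect_lte(max(sizes) - min(sizes), 2L)      # at most 1 per class stratum
  dev_frac <- mean(fd$label == "malignant")
  for (f in 1:5) {
    ff <- mean(fd$label[fd$fold == f] == "malignant")
    expect_lt(abs(ff - dev_frac), 0.05)
  }
  expect_error(stratified_kfold_patients(make_table(6, 0.5, 8), k = 5),
               "at least k")
})

test_that("no patient leaks across test and folds for any seed", {
  tab <- make_table(30, 0.4, 9)
  for (seed in 1:100) {
    sp <- patient_level_split(tab, 0.2, seed = seed)
    dev <- sp$patient_id[sp$partition == "dev"]
    fd <- stratified_kfold_patients(tab[tab$patient_id %in% dev, ], k = 5,
                                    seed = seed)
    expect_length(intersect(sp$patient_id[sp$partition == "test"],
                            fd$patient_id), 0)
    expect_identical(anyDuplicated(fd$patient_id), 0L)
  }
})

test_that("confusion counts match a manual tally", {
  y <- c(1, 1, 0, 0, 1, 0, 1, 0)
  p <- c(1, 0, 0, 1, 1, 0, 0, 1)
  cm <- confusion(y, p)
  expect_identical(cm, list(TP = 2L, TN = 2L, FP = 2L, FN = 2L))
  perfect <- confusion(y, y)
  expect_identical(perfect$FP + perfect$FN, 0L)
  inverted <- confusion(y, 1 - y)
  expect_identical(inverted$TP + inverted$TN, 0L)
  expect_error(confusion(c(0, 2), c(0, 1)), "0/1")
})

test_that("threshold metrics match hand-computed formulas and conventions", {
  perfect <- metrics_from_confusion(list(TP = 5L, TN = 5L, FP = 0L, FN = 0L))
  expect_true(all(unlist(perfect) == 1))
  m <- metrics_from_confusion(list(TP = 45L, TN = 40L, FP = 5L, FN = 10L))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 45 / 50)
  expect_equal(m$recall, 45 / 55)
  expect_equal(m$f1, 2 * (45/50) * (45/55) / ((45/50) + (45/55)))
  expect_equal(m$mcc, (45*40 - 5*10) / sqrt(50 * 55 * 45 * 50))
  po <- 0.85; pe <- (50*55 + 50*45) / 100^2
  expect_equal(m$kappa, (po - pe) / (1 - pe))
  degenerate <- metrics_from_confusion(list(TP = 0L, TN = 10L, FP = 0L, FN = 0L))
  expect_identical(degenerate$precision, 0)
  expect_identical(degenerate$recall, 0)
  expect_identical(degenerate$mcc, 0)
  expect_identical(degenerate$kappa, 0)     # chance agreement = 1
})

test_that("AUROC equals the exhaustive pairwise statistic", {
  s <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.2)
  y <- c(1, 1, 0, 1, 0, 0)
  pairwise <- function(s, y) {
    sp <- s[y == 1]; sn <- s[y == 0]
    mean(outer(sp, sn, ">") + 0.5 * outer(sp, sn, "=="))
  }
  expect_equal(auroc(s, y), pairwise(s, y))
  expect_identical(auroc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_identical(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  set.seed(10)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)                 # coarse scores force ties
    expect_equal(auroc(s, y), pairwise(s, y))
  }
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:10) {
    y <- c(0, 1, rbinom(28, 1, 0.4))
    s <- runif(30)
    ref <- suppressMessages(as.numeric(pROC::auc(
      pROC::roc(y, s, quiet = TRUE, direction = "<", levels = c(0, 1)))))
    expect_equal(auroc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("AUPRC step integration matches a direct sweep", {
  s <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.2)
  y <- c(1, 1, 0, 1, 0, 0)
  # direct: walk thresholds over sorted scores, record (recall, precision)
  ths <- sort(unique(s), decreasing = TRUE)
  rec <- vapply(ths, function(t) sum(y[s >= t]) / sum(y), numeric(1))
  prec <- vapply(ths, function(t) sum(y[s >= t]) / sum(s >= t), numeric(1))
  expect_equal(auprc(s, y), sum(diff(c(0, rec)) * prec))
  expect_identical(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_error(auprc(1:3, c(0, 0, 0)), "both classes")
})

test_that("fold aggregation uses the arithmetic mean and sample SD", {
  folds <- data.frame(m = c(1, 2, 3))
  agg <- cv_aggregate(folds)
  expect_equal(agg["mean", "m"], 2)
  expect_equal(agg["sd", "m"], 1)
  same <- cv_aggregate(data.frame(m = rep(0.7, 5)))
  expect_equal(same["sd", "m"], 0)
  single <- cv_aggregate(data.frame(m = 0.9))
  expect_equal(single["sd", "m"], 0)
  expect_error(cv_aggregate(data.frame()))
})

test_that("metric consistency: stored F1 is the harmonic mean of precision and recall", {
  set.seed(12)
  for (i in 1:20) {
    y <- c(0, 1, rbinom(30, 1, 0.4))
    s <- runif(32)
    row <- metrics_from_scores(s, y)
    expect_equal(row$f1, f1_score(row$precision, row$recall), tolerance = 1e-12)
  }
})

test_that("percentile bootstrap honors degenerate and enumerable cases", {
  ci <- bootstrap_ci(rep(0.7, 5), B = 200, seed = 13)
  expect_identical(c(ci$lower, ci$upper), c(0.7, 0.7))
  a <- bootstrap_ci(c(1, 2, 4), B = 500, seed = 14)
  b <- bootstrap_ci(c(1, 2, 4), B = 500, seed = 14)
  expect_identical(a, b)
  # two values {0,1}: the 4 equally likely resamples have means {0,.5,.5,1},
  # so at B = 10000 both extremes appear beyond the 2.5% tails
  ci2 <- bootstrap_ci(c(0, 1), B = 10000, seed = 15)
  expect_identical(c(ci2$lower, ci2$upper), c(0, 1))
  vals <- c(0.2, 0.9, 0.4, 0.6)
  ci3 <- bootstrap_ci(vals, B = 10000, seed = 16)
  expect_lte(ci3$lower, mean(vals)); expect_gte(ci3$upper, mean(vals))
})

test_that("dataset summaries report image-per-patient statistics", {
  tab <- data.frame(patient_id = c("a", "b", "b", "b"))
  s <- dataset_summary(tab)
  expect_identical(s$n_patients, 2L)
  expect_identical(s$n_images, 4L)
  expect_equal(s$images_per_patient_mean, 2)
  tab1 <- data.frame(patient_id = letters[1:5])
  s1 <- dataset_summary(tab1)
  expect_equal(s1$images_per_patient_mean, 1)
  expect_equal(s1$images_per_patient_sd, 0)
})
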