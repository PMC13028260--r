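#' Patient-level evaluation protocol
#'
#' Patient-grouped stratified partitioning (80/20 development/test by
#' default), stratified k-fold cross-validation on the development patients,
#' the binary metric suite (malignant = positive class throughout),
#' fold aggregation as mean and sample SD, and percentile bootstrap
#' confidence intervals.
#'
#' @name evalproto
NULL

# one label per patient: majority over its images, ties -> malignant
# (screening-conservative)
patient_labels <- function(table) {
  stopifnot(all(c("patient_id", "label") %in% names(table)))
  stopifnot(all(table$label %in% c("benign", "malignant")))
  tab <- tapply(table$label == "malignant", table$patient_id, mean)
  ifelse(tab >= 0.5, "malignant", "benign")
}

# largest-remainder allocation of a total quota across strata
quota_alloc <- function(n_per_class, frac) {
  total <- round(frac * sum(n_per_class))
  exact <- frac * n_per_class
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

#' Patient-level stratified development/test split
#'
#' Every image of a patient shares the patient's partition, so no patient
#' (and no image) can leak across the split. Stratified by patient-level
#' label with largest-remainder rounding, so the test set holds
#' `round(test_frac * n_patients)` patients with class proportions as close
#' to the global ones as integer counts allow.
#'
#' @param table data.frame with `patient_id`, `label`
#'   (benign/malignant), one row per image.
#' @param test_frac fraction of patients held out (default 0.2).
#' @param seed integer seed.
#' @return data.frame `patient_id`, `label` (patient-level), `partition`
#'   (`"dev"`/`"test"`).
#' @export
patient_level_split <- function(table, test_frac = 0.2, seed = 1L) {
  pl <- patient_labels(table)
  pids <- names(pl)
  counts <- table(factor(pl, levels = c("benign", "malignant")))
  if (any(counts < 2)) stop("each class needs at least 2 patients")
  counts <- counts[counts > 0]
  with_seed(seed, {
    out <- data.frame(patient_id = pids, label = unname(pl),
                      partition = "dev", stringsAsFactors = FALSE)
    quotas <- quota_alloc(as.numeric(counts), test_frac)
    names(quotas) <- names(counts)
    for (cl in names(counts)) {
      members <- pids[pl == cl]
      take <- sample(members, quotas[[cl]])
      out$partition[out$patient_id %in% take] <- "test"
    }
    out
  })
}

#' Stratified k-fold assignment of development patients
#'
#' Shuffles patients within each class and deals them round-robin over the
#' folds, so each patient lands in exactly one fold, fold sizes differ by at
#' most one patient per class, and class proportions stay balanced.
#'
#' @param dev_table image-level data.frame of development patients
#'   (`patient_id`, `label`).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return data.frame `patient_id`, `label`, `fold` (1..k).
#' @export
stratified_kfold_patients <- function(dev_table, k = 5L, seed = 1L) {
  pl <- patient_labels(dev_table)
  if (any(table(factor(pl, levels = c("benign", "malignant"))) < k))
    stop("need at least k patients per class")
  with_seed(seed, {
    fold <- integer(length(pl))
    names(fold) <- names(pl)
    offset <- 0L
    for (cl in unique(pl)) {
      members <- sample(names(pl)[pl == cl])
      fold[members] <- ((seq_along(members) - 1L + offset) %% k) + 1L
      offset <- offset + length(members)   # stagger classes across folds
    }
    data.frame(patient_id = names(fold), label = unname(pl[names(fold)]),
               fold = unname(fold), stringsAsFactors = FALSE)
  })
}

#' Binary confusion matrix (malignant = positive)
#'
#' @param y_true,y_pred integer vectors in {0, 1} (1 = malignant).
#' @return list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (!all(c(y_true, y_pred) %in% c(0, 1))) stop("labels must be 0/1")
  list(TP = sum(y_true == 1 & y_pred == 1),
       TN = sum(y_true == 0 & y_pred == 0),
       FP = sum(y_true == 0 & y_pred == 1),
       FN = sum(y_true == 1 & y_pred == 0))
}

#' Threshold metrics from a confusion matrix
#'
#' Standard formulas with fixed zero-division conventions: precision and
#' recall are 0 when their denominator is 0; MCC is 0 when any marginal is
#' 0; kappa is 0 when chance agreement is 1. All values in [0, 1].
#'
#' @param cm result of [confusion()].
#' @return list with `accuracy`, `precision`, `recall`, `f1`, `mcc`,
#'   `kappa`.
#' @export
metrics_from_confusion <- function(cm) {
  TP <- cm$TP; TN <- cm$TN; FP <- cm$FP; FN <- cm$FN
  n <- TP + TN + FP + FN
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  recall <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- f1_score(precision, recall)
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom > 0) (TP * TN - FP * FN) / sqrt(denom) else 0
  po <- (TP + TN) / n
  pe <- ((TP + FP) * (TP + FN) + (TN + FN) * (TN + FP)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 0
  list(accuracy = po, precision = precision, recall = recall, f1 = f1,
       mcc = mcc, kappa = kappa)
}

#' Harmonic mean of precision and recall
#'
#' Accepts values on either the [0, 1] or the percentage scale (the result
#' is on the input scale); returns 0 when both inputs are 0.
#'
#' @param precision,recall nonnegative values on a common scale.
#' @return the F1 score on the same scale.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall <= 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Area under the ROC curve (rank statistic)
#'
#' `P(score_pos > score_neg) + 0.5 P(score_pos = score_neg)` over all
#' positive-negative pairs, computed from midranks.
#'
#' @param scores numeric scores (higher = more malignant).
#' @param labels 0/1 labels (1 = malignant).
#' @return value in [0, 1].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("auroc needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve (step integration)
#'
#' Thresholds descend over the distinct score values (ties grouped); the
#' area is the sum of `(R_i - R_{i-1}) * P_i` over achieved
#' (recall, precision) points, malignant = positive.
#'
#' @inheritParams auroc
#' @return value in [0, 1].
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  npos <- sum(labels == 1)
  if (npos == 0 || npos == length(labels)) stop("auprc needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(1 - y)[grp_end]
  recall <- tp / npos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Full metric row from continuous scores
#'
#' Thresholds the malignant score at 0.5 for the confusion-based metrics
#' and adds AUROC/AUPRC.
#'
#' @inheritParams auroc
#' @param threshold decision threshold on the malignant score.
#' @return one-row data.frame of the eight metrics (threshold metrics in
#'   the reference column order: precision, recall, f1, accuracy, mcc,
#'   kappa, then auroc and auprc), values in [0, 1].
#' @export
metrics_from_scores <- function(scores, labels, threshold = 0.5) {
  cm <- confusion(labels, as.integer(scores >= threshold))
  m <- metrics_from_confusion(cm)
  data.frame(precision = m$precision, recall = m$recall, f1 = m$f1,
             accuracy = m$accuracy, mcc = m$mcc, kappa = m$kappa,
             auroc = auroc(scores, labels), auprc = auprc(scores, labels))
}

#' Aggregate per-fold metrics
#'
#' Arithmetic mean and sample (n-1) standard deviation per metric column;
#' a single fold yields SD 0 by convention.
#'
#' @param folds data.frame of per-fold metric rows (numeric columns).
#' @return data.frame with rows `mean` and `sd`.
#' @export
cv_aggregate <- function(folds) {
  if (is.null(dim(folds)) || nrow(folds) < 1) stop("need at least one fold")
  num <- folds[vapply(folds, is.numeric, logical(1))]
  means <- vapply(num, mean, numeric(1))
  sds <- if (nrow(num) > 1) vapply(num, stats::sd, numeric(1)) else
    stats::setNames(rep(0, ncol(num)), names(num))
  out <- rbind(mean = means, sd = sds)
  as.data.frame(out)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the values with replacement `B` times, takes the mean of each
#' resample, and returns the `(1-level)/2` and `1-(1-level)/2` empirical
#' percentiles. Seed-reproducible.
#'
#' @param values numeric vector (e.g. per-fold metric values).
#' @param B bootstrap iterations (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with `lower`, `upper`, `B`, `level`.
#' @export
bootstrap_ci <- function(values, B = 10000L, level = 0.95, seed = 1L) {
  stopifnot(length(values) >= 1, B >= 1)
  with_seed(seed, {
    means <- vapply(seq_len(B), function(i)
      mean(sample(values, length(values), replace = TRUE)), numeric(1))
    qs <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
    list(lower = qs[1], upper = qs[2], B = B, level = level)
  })
}

#' Cohort summary statistics
#'
#' @param table image-level data.frame with `patient_id`.
#' @return list with `n_patients`, `n_images`, `images_per_patient_mean`,
#'   `images_per_patient_sd`.
#' @export
dataset_summary <- function(table) {
  stopifnot(nrow(table) >= 1)
  counts <- as.numeric(table(table$patient_id))
  list(n_patients = length(counts), n_images = nrow(table),
       images_per_patient_mean = mean(counts),
       images_per_patient_sd = if (length(counts) > 1) stats::sd(counts) else 0)
}
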