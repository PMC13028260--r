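#' Training engine
#'
#' AdamW with decoupled weight decay, cosine-annealed learning rate with
#' linear warm-up, an exponential moving average of the weights, MixUp-aware
#' loss wiring, full seeding, and the structural ablation harness.
#'
#' @name engine
NULL

#' Cosine-annealed learning rate with linear warm-up
#'
#' Linear ramp from 0 to `base_lr` over `warmup_steps`, then
#' `floor + (base_lr - floor) * (1 + cos(pi * progress)) / 2` down to
#' `floor` at `total_steps`.
#'
#' @param step current step (0-based, up to `total_steps`).
#' @param total_steps total schedule length.
#' @param base_lr peak learning rate.
#' @param warmup_steps warm-up length (must be < `total_steps`).
#' @param floor terminal learning rate (default 0).
#' @return learning rate at `step`.
#' @export
cosine_lr <- function(step, total_steps, base_lr, warmup_steps = 0L,
                      floor = 0) {
  stopifnot(step >= 0, step <= total_steps)
  if (warmup_steps >= total_steps) stop("warmup must be shorter than the schedule")
  if (step < warmup_steps) return(base_lr * step / warmup_steps)
  progress <- (step - warmup_steps) / (total_steps - warmup_steps)
  floor + (base_lr - floor) * 0.5 * (1 + cos(pi * progress))
}

#' Exponential moving average of a parameter tree
#'
#' `ema <- decay * ema + (1 - decay) * weights`, per parameter.
#'
#' @param ema_weights,weights parameter trees of identical structure.
#' @param decay in [0, 1).
#' @return updated tree.
#' @export
ema_update <- function(ema_weights, weights, decay = 0.999) {
  stopifnot(decay >= 0, decay <= 1)
  tree_map2(function(e, w) decay * e + (1 - decay) * w, ema_weights, weights)
}

# AdamW on flattened parameter vectors (decoupled weight decay)
adamw_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adamw_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.05) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * theta)
  list(theta = theta, state = state)
}

#' Training configuration
#'
#' Defaults follow the reference recipe: AdamW at learning rate 1e-4 with
#' weight decay 0.05, batch size 16, 80 epochs, cosine annealing with a
#' warm-up of 5% of total steps, EMA decay 0.999, global seed 42, CLAHE
#' clip 2.0, RandAugment N=2 M=9 with +/-10 degree rotations and horizontal
#' flips, MixUp alpha 0.3, t-kernel alpha 3 with clustering weight 0.5.
#'
#' @param ... overrides of any default field.
#' @return list of class `train_config`.
#' @export
train_config <- function(...) {
  cfg <- list(lr = 1e-4, weight_decay = 0.05, batch_size = 16L, epochs = 80L,
              warmup_frac = 0.05, ema_decay = 0.999, seed = 42L,
              preset = "tiny", variant = "full",
              alpha = 3, learnable_alpha = FALSE, lambda_proto = 0.5,
              clahe = TRUE, clip_limit = 2.0,
              augment = TRUE, ra_n = 2L, ra_m = 9L, rotation_limit_deg = 10,
              hflip_prob = 0.5, use_mixup = TRUE, mixup_alpha = 0.3)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$lr > 0, cfg$weight_decay >= 0, cfg$ema_decay >= 0,
            cfg$ema_decay < 1, cfg$batch_size >= 1, cfg$epochs >= 1)
  structure(cfg, class = "train_config")
}

#' Load a training configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [train_config()] fields.
#' @return a `train_config`.
#' @export
load_train_config <- function(path) {
  do.call(train_config, yaml::read_yaml(path))
}

config_policy <- function(config) {
  augmentation_policy(n_ops = config$ra_n, magnitude = config$ra_m,
                      rotation_limit_deg = config$rotation_limit_deg,
                      hflip_prob = config$hflip_prob)
}

# stochastic batch augmentation: per-image geometric + RandAugment, then
# batch-level MixUp; returns images plus soft labels
augment_batch <- function(images, labels01, config) {
  policy <- config_policy(config)
  if (config$augment) {
    images <- lapply(images, function(im)
      rand_augment(random_geometric_augment(im, policy),
                   policy$n_ops, policy$magnitude))
  }
  soft <- one_hot(labels01)
  if (config$use_mixup && length(images) >= 2) {
    mx <- mixup(images, soft, config$mixup_alpha)
    images <- mx$images
    soft <- mx$soft_labels
  }
  list(images = images, labels = soft)
}

#' Train a model
#'
#' Per step: draw the next shuffled batch, apply online augmentation and
#' MixUp (training data only), compute the loss (prototype-head composite
#' loss or soft-label cross-entropy for softmax-head variants), take one
#' AdamW step under the cosine schedule, and update the EMA shadow weights.
#' Fully seeded: the same seed reproduces the loss trajectory bit-for-bit
#' on CPU. Aborts with a diagnostic if the loss turns non-finite.
#'
#' @param model a `mammofuse_model` whose preset matches the image size.
#' @param images list of preprocessed training images.
#' @param labels01 integer labels (0 benign, 1 malignant).
#' @param config a [train_config()].
#' @param steps optional total step count (otherwise `epochs` x batches per
#'   epoch).
#' @return list with `model` (trained), `ema_model` (EMA weights),
#'   `history` (per-step data.frame), `first_batch` (the first augmented
#'   batch, retained so pipelines can be compared across runs).
#' @export
train <- function(model, images, labels01, config = train_config(),
                  steps = NULL) {
  stopifnot(length(images) >= 1, length(images) == length(labels01))
  n <- length(images)
  batch_size <- min(config$batch_size, n)
  steps_per_epoch <- ceiling(n / batch_size)
  total_steps <- steps %||% (config$epochs * steps_per_epoch)
  warmup <- min(max(1L, round(config$warmup_frac * total_steps)),
                total_steps - 1L)

  theta <- tree_flatten(model$params)
  opt <- adamw_init(length(theta))
  ema <- theta
  history <- data.frame(step = seq_len(total_steps), lr = NA_real_,
                        loss = NA_real_)
  first_batch <- NULL

  with_seed(config$seed, {
    order_idx <- integer(0)
    for (st in seq_len(total_steps)) {
      if (length(order_idx) < batch_size) order_idx <- sample.int(n)
      take <- order_idx[seq_len(batch_size)]
      order_idx <- order_idx[-seq_len(batch_size)]
      ab <- augment_batch(images[take], labels01[take], config)
      if (st == 1L) first_batch <- ab
      bg <- model_batch_grad(model, ab$images, ab$labels)
      if (!is.finite(bg$loss))
        stop(sprintf("training diverged at step %d (loss = %s)", st, bg$loss))
      lr <- cosine_lr(st - 1L, total_steps, config$lr, warmup)
      up <- adamw_step(theta, tree_flatten(bg$grads), opt, lr,
                       weight_decay = config$weight_decay)
      theta <- up$theta
      opt <- up$state
      model$params <- tree_unflatten(model$params, theta)
      ema <- config$ema_decay * ema + (1 - config$ema_decay) * theta
      history$lr[st] <- lr
      history$loss[st] <- bg$loss
    }
  })
  ema_model <- model
  ema_model$params <- tree_unflatten(model$params, ema)
  list(model = model, ema_model = ema_model, history = history,
       first_batch = first_batch)
}

#' Evaluate a model on labeled images
#'
#' @param model a `mammofuse_model`.
#' @param images list of preprocessed images.
#' @param labels01 integer 0/1 labels.
#' @return one-row metric data.frame (see [metrics_from_scores()]); AUROC
#'   and AUPRC are `NA` if only one class is present.
#' @export
evaluate_model <- function(model, images, labels01) {
  scores <- model_predict(model, images)[, 2]
  if (length(unique(labels01)) < 2) {
    cm <- confusion(labels01, as.integer(scores >= 0.5))
    m <- metrics_from_confusion(cm)
    return(data.frame(precision = m$precision, recall = m$recall, f1 = m$f1,
                      accuracy = m$accuracy, mcc = m$mcc, kappa = m$kappa,
                      auroc = NA_real_, auprc = NA_real_))
  }
  metrics_from_scores(scores, labels01)
}

# deterministic preprocessing of every cohort image at the preset size
preprocess_cohort <- function(cohort, preset, config) {
  lapply(cohort$images, function(im)
    preprocess_pipeline(im, train_mode = FALSE,
                        target_size = preset$input_size,
                        clip_limit = if (config$clahe) config$clip_limit else NULL))
}

cohort_labels01 <- function(table) as.integer(table$label == "malignant")

#' Patient-level cross-validation of a model configuration on a cohort
#'
#' Splits patients 80/20 into development and held-out test, runs
#' stratified k-fold cross-validation at the patient level on the
#' development images (train on k-1 folds, evaluate on the held-out fold),
#' then trains on all development images and evaluates on the test set.
#'
#' @param cohort a [generate_cohort()] result (or an equivalent list with
#'   `table` and `images`).
#' @param config a [train_config()].
#' @param k folds (default 5).
#' @param steps_per_fold optional cap on training steps per fold.
#' @return list with `fold_metrics` (held-out fold metrics plus the
#'   training-partition accuracy per fold in `dev_accuracy`), `aggregate`
#'   (mean/SD rows), `ci` (percentile bootstrap per metric), `holdout`
#'   metrics, `split`, `folds`.
#' @export
crossvalidate_cohort <- function(cohort, config = train_config(), k = 5L,
                                 steps_per_fold = NULL) {
  preset <- backbone_preset(config$preset)
  imgs <- preprocess_cohort(cohort, preset, config)
  tab <- cohort$table
  y <- cohort_labels01(tab)
  split <- patient_level_split(tab, 0.2, seed = config$seed)
  dev_pat <- split$patient_id[split$partition == "dev"]
  dev_rows <- which(tab$patient_id %in% dev_pat)
  folds <- stratified_kfold_patients(tab[dev_rows, ], k, seed = config$seed)

  fold_metrics <- NULL
  for (f in seq_len(k)) {
    fold_pat <- folds$patient_id[folds$fold == f]
    va <- dev_rows[tab$patient_id[dev_rows] %in% fold_pat]
    tr <- setdiff(dev_rows, va)
    m <- build_model(preset, config$variant, alpha = config$alpha,
                     learnable_alpha = config$learnable_alpha,
                     lambda_proto = config$lambda_proto, seed = config$seed + f)
    fit <- train(m, imgs[tr], y[tr], config, steps = steps_per_fold)
    fm <- evaluate_model(fit$model, imgs[va], y[va])
    fm$dev_accuracy <- evaluate_model(fit$model, imgs[tr], y[tr])$accuracy
    fold_metrics <- rbind(fold_metrics, cbind(fold = f, fm))
  }
  agg <- cv_aggregate(fold_metrics[, -1])
  ci <- lapply(fold_metrics[, setdiff(names(fold_metrics), "fold")],
               function(v) if (all(is.finite(v)))
                 bootstrap_ci(v, B = 10000L, seed = config$seed) else NULL)

  test_rows <- which(!(tab$patient_id %in% dev_pat))
  m <- build_model(preset, config$variant, alpha = config$alpha,
                   learnable_alpha = config$learnable_alpha,
                   lambda_proto = config$lambda_proto, seed = config$seed)
  fit <- train(m, imgs[dev_rows], y[dev_rows], config, steps = steps_per_fold)
  holdout <- evaluate_model(fit$model, imgs[test_rows], y[test_rows])

  list(fold_metrics = fold_metrics, aggregate = agg, ci = ci,
       holdout = holdout, split = split, folds = folds,
       final_model = fit$model)
}

#' The structural ablation grid
#'
#' @return character vector of the six variant ids, in grid order.
#' @export
ablation_variants <- function() MODEL_VARIANTS

#' Run the ablation harness
#'
#' Trains and evaluates each requested variant under an identical
#' patient-level split and identical data pipeline (same preprocessing per
#' variant's CLAHE switch, same seeds), one run per seed, and returns a
#' per-run metric table plus per-variant means.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config a [train_config()] (its `variant` field is ignored).
#' @param variants subset of [ablation_variants()].
#' @param seeds integer vector of training seeds.
#' @param steps training steps per run.
#' @param eval_on `"test"` (held-out patients) or `"dev"` (the development
#'   images the run was trained on; a fitting-capacity comparison for
#'   budgets where held-out estimates would rest on a handful of patients).
#' @return list with `runs` (variant x seed metric rows) and `summary`
#'   (per-variant mean metrics).
#' @export
run_ablation <- function(cohort, config = train_config(),
                         variants = ablation_variants(), seeds = 1L,
                         steps = NULL, eval_on = c("test", "dev")) {
  eval_on <- match.arg(eval_on)
  preset <- backbone_preset(config$preset)
  tab <- cohort$table
  y <- cohort_labels01(tab)
  split <- patient_level_split(tab, 0.2, seed = config$seed)
  dev_pat <- split$patient_id[split$partition == "dev"]
  dev_rows <- which(tab$patient_id %in% dev_pat)
  test_rows <- setdiff(seq_len(nrow(tab)), dev_rows)

  runs <- NULL
  for (v in variants) {
    vcfg <- config
    vcfg$clahe <- config$clahe && variant_flags(v)$use_clahe
    imgs <- preprocess_cohort(cohort, preset, vcfg)
    for (s in seeds) {
      vcfg$seed <- s
      m <- build_model(preset, v, alpha = config$alpha,
                       lambda_proto = config$lambda_proto, seed = s)
      fit <- train(m, imgs[dev_rows], y[dev_rows], vcfg, steps = steps)
      eval_rows <- if (eval_on == "test") test_rows else dev_rows
      em <- evaluate_model(fit$model, imgs[eval_rows], y[eval_rows])
      runs <- rbind(runs, cbind(variant = v, seed = s, em))
    }
  }
  num <- names(runs)[vapply(runs, is.numeric, logical(1))]
  num <- setdiff(num, "seed")
  summary <- stats::aggregate(runs[num], by = list(variant = runs$variant), mean)
  list(runs = runs, summary = summary)
}
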