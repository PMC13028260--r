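#' Model assembly
#'
#' A model bundles a [backbone_preset()], a structural variant, and a
#' parameter tree. Variants mirror the ablation grid: `cnn_only` and
#' `vit_only` classify one pooled stream with a linear softmax head;
#' `passive_fusion` pools and concatenates both streams without
#' cross-attention; `bdcg_no_pash` adds the cross-guidance fusion but keeps
#' the softmax head; `full` (and `full_no_clahe`, which only changes
#' preprocessing) uses fusion plus the prototype head.
#'
#' @name model
NULL

MODEL_VARIANTS <- c("cnn_only", "vit_only", "passive_fusion",
                    "bdcg_no_pash", "full_no_clahe", "full")

variant_flags <- function(variant) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  list(use_local  = variant != "vit_only",
       use_global = variant != "cnn_only",
       use_bdcg   = variant %in% c("bdcg_no_pash", "full_no_clahe", "full"),
       use_pash   = variant %in% c("full_no_clahe", "full"),
       use_clahe  = variant != "full_no_clahe")
}

#' Build a model
#'
#' @param preset preset name or a [backbone_preset()] list.
#' @param variant one of `r paste(MODEL_VARIANTS, collapse = ", ")`.
#' @param alpha Student-t parameter (default 3).
#' @param learnable_alpha optimize alpha through a softplus
#'   reparameterization (initialized at `alpha`)?
#' @param lambda_proto clustering-loss weight (default 0.5).
#' @param proto_scale prototype initialization scale.
#' @param seed seed for parameter initialization.
#' @return an object of class `mammofuse_model`.
#' @export
build_model <- function(preset = "tiny", variant = "full", alpha = 3,
                        learnable_alpha = FALSE, lambda_proto = 0.5,
                        proto_scale = 0.5, seed = NULL) {
  if (is.character(preset)) preset <- backbone_preset(preset)
  flags <- variant_flags(variant)
  nl <- length(preset$local_channels)
  C_L <- preset$local_channels[nl]
  C_G <- preset$global_channels[length(preset$global_channels)]
  D <- (if (flags$use_local) C_L else 0L) + (if (flags$use_global) C_G else 0L)
  params <- with_seed(seed, {
    p <- list()
    if (flags$use_local) p$local <- init_local_encoder(preset)
    if (flags$use_global) p$global <- init_global_encoder(preset)
    if (flags$use_local && flags$use_global)
      p$bdcg <- init_bdcg(C_L, C_G, preset$fusion_heads, preset$fusion_d_head)
    if (flags$use_pash) {
      p$proto <- init_prototypes(2L, D, proto_scale)
      if (learnable_alpha) p$alpha_raw <- raw_from_alpha(alpha)
    } else {
      p$head <- list(W = init_mat(D, 2L) * 0.5, b = rep(0, 2L))
    }
    p
  })
  structure(list(preset = preset, variant = variant, flags = flags,
                 alpha = alpha, learnable_alpha = learnable_alpha,
                 lambda_proto = lambda_proto, D = D, params = params),
            class = "mammofuse_model")
}

model_alpha <- function(model) {
  if (isTRUE(model$learnable_alpha)) alpha_from_raw(model$params$alpha_raw)
  else model$alpha
}

#' @export
print.mammofuse_model <- function(x, ...) {
  cat(sprintf("<mammofuse_model> preset=%s variant=%s D=%d params=%d\n",
              x$preset$name, x$variant, x$D,
              length(tree_flatten(x$params))))
  invisible(x)
}

#' Forward pass for one image
#'
#' Runs the configured streams, fusion and head on a single preprocessed
#' image. With `cache = TRUE` every intermediate needed for the backward
#' pass and for saliency is retained (training and Grad-CAM use this).
#'
#' @param model a `mammofuse_model`.
#' @param image preprocessed image matrix matching the preset input size.
#' @param cache keep intermediates?
#' @return list with `Z` (fused embedding), `posterior` (length-2, benign
#'   then malignant), `map` (pre-pool fused spatial array), and `cache`
#'   when requested.
#' @export
model_forward <- function(model, image, cache = FALSE) {
  fl <- gl <- NULL
  flags <- model$flags
  if (flags$use_local) fl <- local_encode_fwd(image, model$params$local, model$preset)
  if (flags$use_global) gl <- global_encode_fwd(image, model$params$global, model$preset)

  if (flags$use_local && flags$use_global) {
    hw_L <- fl$cache$final_hw
    FLt <- grid_to_tokens(fl$out)
    fz <- bdcg_fwd(FLt, gl$out, hw_L, c(gl$h, gl$w), model$params$bdcg,
                   model$preset$fusion_heads, model$preset$fusion_d_head,
                   enable = flags$use_bdcg)
    Z <- fz$Z; map <- fz$map
  } else if (flags$use_local) {
    FLt <- grid_to_tokens(fl$out)
    Z <- colMeans(FLt); map <- fl$out; fz <- NULL
  } else {
    Z <- colMeans(gl$out); map <- tokens_to_grid(gl$out, gl$h, gl$w); fz <- NULL
  }

  if (flags$use_pash) {
    post <- t_kernel_posterior(squared_distance(Z, model$params$proto),
                               model_alpha(model))
  } else {
    logits <- drop(Z %*% model$params$head$W) + model$params$head$b
    post <- matrix(softmax_rows(matrix(logits, 1)), 1)
  }
  out <- list(Z = Z, posterior = drop(post), map = map)
  if (cache) out$cache <- list(fl = fl, gl = gl, fz = fz)
  out
}

# accumulate two parameter-gradient trees
acc_grads <- function(a, b) if (is.null(a)) b else tree_map2(`+`, a, b)

# loss + full parameter gradients on a batch (list of images, soft labels)
model_batch_grad <- function(model, images, labels) {
  n <- length(images)
  fwd <- lapply(images, function(im) model_forward(model, im, cache = TRUE))
  Z <- do.call(rbind, lapply(fwd, `[[`, "Z"))
  flags <- model$flags

  dparams <- NULL
  if (flags$use_pash) {
    pl <- pash_loss(Z, model$params$proto, labels, model_alpha(model),
                    model$lambda_proto, grads = TRUE)
    loss <- pl$total
    dZ <- pl$dZ
    head_grads <- list(proto = pl$dP)
    if (isTRUE(model$learnable_alpha))
      head_grads$alpha_raw <- pl$dalpha * dalpha_draw(model$params$alpha_raw)
    posterior <- pl$posterior
  } else {
    logits <- sweep(Z %*% model$params$head$W, 2, model$params$head$b, "+")
    posterior <- softmax_rows(logits)
    loss <- -sum(labels * log(pmax(posterior, 1e-300))) / n
    dlogits <- (posterior * rowSums(labels) - labels) / n
    head_grads <- list(head = list(W = crossprod(Z, dlogits),
                                   b = colSums(dlogits)))
    dZ <- dlogits %*% t(model$params$head$W)
  }

  enc_grads <- NULL
  for (i in seq_len(n)) {
    f <- fwd[[i]]
    gi <- list()
    if (flags$use_local && flags$use_global) {
      bb <- bdcg_bwd(dZ[i, ], f$cache$fz$cache, model$params$bdcg)
      gi$bdcg <- bb$dparams
      dFL_grid <- tokens_to_grid(bb$dFL, f$cache$fl$cache$final_hw[1],
                                 f$cache$fl$cache$final_hw[2])
      gi$local <- local_encode_bwd(dFL_grid, f$cache$fl$cache,
                                   model$params$local, model$preset)$dparams
      gi$global <- global_encode_bwd(bb$dFG, f$cache$gl$cache,
                                     model$params$global, model$preset)$dparams
    } else if (flags$use_local) {
      hw <- f$cache$fl$cache$final_hw
      nt <- hw[1] * hw[2]
      dFL_grid <- tokens_to_grid(matrix(dZ[i, ], nt, ncol(dZ), byrow = TRUE) / nt,
                                 hw[1], hw[2])
      gi$local <- local_encode_bwd(dFL_grid, f$cache$fl$cache,
                                   model$params$local, model$preset)$dparams
    } else {
      nt <- nrow(f$cache$gl$out)
      dFG <- matrix(dZ[i, ], nt, ncol(dZ), byrow = TRUE) / nt
      gi$global <- global_encode_bwd(dFG, f$cache$gl$cache,
                                     model$params$global, model$preset)$dparams
    }
    enc_grads <- acc_grads(enc_grads, gi)
  }
  grads <- c(enc_grads, head_grads)
  grads <- grads[names(model$params)]
  list(loss = loss, grads = grads, posterior = posterior, Z = Z)
}

#' Predict class posteriors for a list of images
#'
#' @param model a `mammofuse_model`.
#' @param images list of preprocessed image matrices.
#' @return `n x 2` matrix of posteriors (column 2 = malignant).
#' @export
model_predict <- function(model, images) {
  do.call(rbind, lapply(images, function(im) model_forward(model, im)$posterior))
}

#' Save / load a model checkpoint
#'
#' Checkpoints serialize the whole model object (preset, variant, parameter
#' tree, head configuration). Parameter keys follow the stable
#' `component/subcomponent/...` naming of [checkpoint_keys()].
#'
#' @param model a `mammofuse_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) saveRDS(model, path)

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' @rdname save_checkpoint
#' @return `checkpoint_keys`: character vector of slash-separated parameter
#'   names in flattening order.
#' @export
checkpoint_keys <- function(model) {
  walk <- function(tree, prefix) {
    if (is.list(tree)) {
      nm <- names(tree) %||% as.character(seq_along(tree))
      unlist(lapply(seq_along(tree), function(i)
        walk(tree[[i]], paste0(prefix, "/", nm[i]))))
    } else {
      sub("^/", "", prefix)
    }
  }
  walk(model$params, "")
}
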