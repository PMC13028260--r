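#' Gradient-weighted class activation mapping
#'
#' Saliency for a chosen class: per-channel weights are the spatial mean of
#' the class-score gradient at a spatial layer, the map is the rectified
#' weighted channel sum, optionally upsampled to the input and
#' max-normalized for display. The class score backpropagated is the
#' unnormalized log-kernel value `-((alpha+1)/2) log(1 + d_c/alpha)` for
#' prototype-head models (the analogue of a pre-softmax logit) and the raw
#' logit for softmax-head variants.
#'
#' @name gradcam
NULL

#' Capture activations and class-score gradients at a spatial layer
#'
#' Runs a forward pass, forms the class score, and backpropagates it to the
#' requested layer: `"fused"` (default; the pre-pool channel-concatenated
#' map actually classified), `"local"` (local stream final stage), or
#' `"global"` (global stream final stage).
#'
#' @param model a `mammofuse_model`.
#' @param image preprocessed input image.
#' @param class_index 0 = benign, 1 = malignant.
#' @param layer which spatial layer to capture.
#' @return list with `maps` and `grads` (`h x w x K` arrays of identical
#'   shape), `class_index`, `class_score`, `layer`.
#' @export
capture_activations <- function(model, image, class_index = 1L,
                                layer = c("fused", "local", "global")) {
  layer <- match.arg(layer)
  flags <- model$flags
  if (layer == "local" && !flags$use_local) stop("model has no local stream")
  if (layer == "global" && !flags$use_global) stop("model has no global stream")
  f <- model_forward(model, image, cache = TRUE)
  Z <- f$Z
  kc <- class_index + 1L

  if (flags$use_pash) {
    d <- squared_distance(Z, model$params$proto)[1, ]
    alpha <- model_alpha(model)
    score <- -((alpha + 1) / 2) * log1p(d[kc] / alpha)
    # d score / d Z through the selected class distance only
    dZ <- -((alpha + 1) / 2) / (alpha + d[kc]) * 2 * (Z - model$params$proto[kc, ])
  } else {
    logits <- drop(Z %*% model$params$head$W) + model$params$head$b
    score <- logits[kc]
    dZ <- model$params$head$W[, kc]
  }

  both <- flags$use_local && flags$use_global
  if (layer == "fused" || !both) {
    maps <- f$map
    hw <- dim(maps)[1:2]
    # Z is the per-channel spatial mean of the fused map, so the gradient
    # spreads uniformly over cells
    grads <- array(rep(dZ, each = hw[1] * hw[2]) / (hw[1] * hw[2]), dim(maps))
  } else {
    bb <- bdcg_bwd(dZ, f$cache$fz$cache, model$params$bdcg)
    if (layer == "local") {
      hw <- f$cache$fl$cache$final_hw
      maps <- f$cache$fl$out
      grads <- tokens_to_grid(bb$dFL, hw[1], hw[2])
    } else {
      maps <- tokens_to_grid(f$cache$gl$out, f$cache$gl$h, f$cache$gl$w)
      grads <- tokens_to_grid(bb$dFG, f$cache$gl$h, f$cache$gl$w)
    }
  }
  stopifnot(identical(dim(maps), dim(grads)))
  list(maps = maps, grads = grads, class_index = class_index,
       class_score = score, layer = layer)
}

#' Per-channel importance weights
#'
#' Spatial mean of the captured gradients, one weight per feature channel.
#'
#' @param bundle result of [capture_activations()].
#' @return numeric vector, length = channel count.
#' @export
channel_weights <- function(bundle) {
  d <- dim(bundle$grads)
  colMeans(matrix(bundle$grads, d[1] * d[2], d[3]))
}

#' Compose the saliency map
#'
#' `ReLU(sum_k w_k A_k)`; optionally bilinearly upsampled to `upsample_to`
#' (side length or `c(h, w)`) and max-normalized to [0, 1] for display (a
#' zero map stays zero).
#'
#' @param bundle result of [capture_activations()] (or any list with a
#'   `maps` array).
#' @param weights per-channel weights, e.g. [channel_weights()].
#' @param upsample_to optional output size.
#' @param normalize divide by the map maximum when positive?
#' @return nonnegative matrix.
#' @export
compute_cam <- function(bundle, weights, upsample_to = NULL, normalize = FALSE) {
  d <- dim(bundle$maps)
  if (length(weights) != d[3]) stop("weights length must equal channel count")
  L <- matrix(matrix(bundle$maps, d[1] * d[2], d[3]) %*% weights, d[1], d[2])
  L <- pmax(L, 0)
  if (!is.null(upsample_to)) {
    mx <- max(L)
    L <- if (mx > 0) resize_to_input(L / mx, upsample_to) * mx
         else matrix(0, if (length(upsample_to) == 1) upsample_to else upsample_to[1],
                     if (length(upsample_to) == 1) upsample_to else upsample_to[2])
  }
  if (normalize && max(L) > 0) L <- L / max(L)
  L
}

#' One-call Grad-CAM
#'
#' @inheritParams capture_activations
#' @param upsample logical; upsample to the input size?
#' @return saliency matrix (input-sized when `upsample = TRUE`),
#'   max-normalized to [0, 1].
#' @export
grad_cam <- function(model, image, class_index = 1L,
                     layer = c("fused", "local", "global"), upsample = TRUE) {
  b <- capture_activations(model, image, class_index, layer)
  compute_cam(b, channel_weights(b),
              upsample_to = if (upsample) dim(image) else NULL,
              normalize = TRUE)
}
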