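#' Prototype-anchored similarity head
#'
#' Classification by proximity: one learnable prototype vector per class
#' (benign = class 0, malignant = class 1) in the fused embedding space,
#' squared Euclidean distances, and a Student-t kernel posterior
#' `p_k = (1 + d_k / alpha)^(-(alpha+1)/2) / sum_j (...)` computed in log
#' space. The loss is soft-label cross-entropy on the posteriors plus
#' `lambda_proto` times a clustering term pulling each embedding toward its
#' label-weighted prototype. Gradients for embeddings, prototypes and the
#' (optionally learnable) alpha are exact and finite-difference-tested.
#'
#' @name pash
NULL

#' Squared Euclidean distances to the prototypes
#'
#' @param Z embedding matrix `n x D` (a single vector is accepted).
#' @param P prototype matrix `K x D`.
#' @return `n x K` matrix of nonnegative distances `||Z - P_k||^2`.
#' @export
squared_distance <- function(Z, P) {
  if (is.null(dim(Z))) Z <- matrix(Z, 1)
  if (ncol(Z) != ncol(P))
    stop("dimension mismatch: embeddings are ", ncol(Z), "-d, prototypes ",
         ncol(P), "-d")
  z2 <- rowSums(Z^2)
  p2 <- rowSums(P^2)
  d <- outer(z2, p2, "+") - 2 * Z %*% t(P)
  pmax(d, 0)                                   # guard tiny negative round-off
}

#' Student-t kernel posterior over classes
#'
#' `p_k` proportional to `(1 + d_k/alpha)^(-(alpha+1)/2)`; smaller distance,
#' larger posterior, strictly monotonically. Computed in log space so the
#' normalization holds to near machine precision for alpha from 0.5 to 1e6.
#' As alpha grows the posterior approaches the Gaussian limit
#' `p_k` proportional to `exp(-d_k / 2)`.
#'
#' @param d `n x K` matrix (or length-K vector) of squared distances.
#' @param alpha positive degrees-of-freedom parameter (default 3).
#' @return `n x K` matrix of class probabilities, rows summing to 1.
#' @export
t_kernel_posterior <- function(d, alpha = 3) {
  stopifnot(alpha > 0)
  if (is.null(dim(d))) d <- matrix(d, 1)
  if (!all(is.finite(d))) stop("non-finite distances")
  logw <- -((alpha + 1) / 2) * log1p(d / alpha)
  softmax_rows(logw)
}

#' Initialize prototypes
#'
#' i.i.d. Gaussian entries at the given scale; seed-reproducible.
#'
#' @param K number of classes (rows).
#' @param D embedding dimension.
#' @param scale standard deviation of the initial entries.
#' @param seed optional seed.
#' @return `K x D` matrix.
#' @export
init_prototypes <- function(K = 2L, D, scale = 0.1, seed = NULL) {
  with_seed(seed, matrix(stats::rnorm(K * D, sd = scale), K, D))
}

#' Composite head loss (cross-entropy + prototype clustering)
#'
#' `ce` is the soft-label cross-entropy of the t-kernel posteriors (the head
#' replaces a softmax layer, so the posteriors themselves are the predicted
#' distribution); `proto` is the batch mean of `sum_k y_k ||Z - P_k||^2`, so
#' MixUp soft labels pull toward both prototypes in proportion to their
#' mixing mass; `total = ce + lambda_proto * proto`.
#'
#' @param Z `n x D` embedding batch.
#' @param P `K x D` prototypes.
#' @param labels `n x K` one-hot or soft label matrix.
#' @param alpha t-kernel parameter.
#' @param lambda_proto weight of the clustering term (default 0.5).
#' @param grads also return gradients w.r.t. `Z`, `P` and `alpha`?
#' @return list with `ce`, `proto`, `total`, `posterior`, and (with
#'   `grads = TRUE`) `dZ`, `dP`, `dalpha`.
#' @export
pash_loss <- function(Z, P, labels, alpha = 3, lambda_proto = 0.5,
                      grads = FALSE) {
  if (is.null(dim(Z))) Z <- matrix(Z, 1)
  stopifnot(nrow(Z) == nrow(labels), ncol(labels) == nrow(P))
  n <- nrow(Z)
  d <- squared_distance(Z, P)
  post <- t_kernel_posterior(d, alpha)
  logp <- log(pmax(post, 1e-300))              # clamped log guard
  if (any(post == 0 & labels > 0))
    warning("zero posterior with positive label mass; log clamped")
  ce <- -sum(labels * logp) / n
  proto <- sum(labels * d) / n
  total <- ce + lambda_proto * proto
  out <- list(ce = ce, proto = proto, total = total, posterior = post)
  if (grads) {
    # d total / d s_k with s_k the log-kernel score: (p_k - y_k)/n for rows
    # normalized so labels sum to 1
    rs <- rowSums(labels)
    dlogit <- (post * rs - labels) / n
    dsd <- -((alpha + 1) / 2) / (alpha + d)    # d s_k / d d_k
    dd <- dlogit * dsd + lambda_proto * labels / n
    diffZ <- array(0, dim(Z))
    dP <- matrix(0, nrow(P), ncol(P))
    for (k in seq_len(nrow(P))) {
      delta <- sweep(Z, 2, P[k, ], "-")
      diffZ <- diffZ + 2 * dd[, k] * delta
      dP[k, ] <- -2 * colSums(dd[, k] * delta)
    }
    # d s_k / d alpha for the learnable-alpha option
    dsa <- -0.5 * log1p(d / alpha) + ((alpha + 1) / 2) * d / (alpha * (alpha + d))
    out$dZ <- diffZ
    out$dP <- dP
    out$dalpha <- sum(dlogit * dsa)
    out$distances <- d
  }
  out
}

#' Predict class posteriors from prototypes
#'
#' Argmax posterior with the posterior maximum as the confidence. An exact
#' tie is resolved deterministically to class index 0 with confidence 0.5
#' and flagged as ambiguous.
#'
#' @param Z embedding matrix `n x D` or a single vector.
#' @param P `K x D` prototypes.
#' @param alpha t-kernel parameter.
#' @return data.frame with `predicted_class` (0-based), `confidence`,
#'   `ambiguous`, and posterior columns `p0 ... p(K-1)`.
#' @export
pash_predict <- function(Z, P, alpha = 3) {
  post <- t_kernel_posterior(squared_distance(Z, P), alpha)
  cls <- max.col(post, ties.method = "first") - 1L
  conf <- post[cbind(seq_len(nrow(post)), cls + 1L)]
  amb <- apply(post, 1, function(p) sum(p == max(p)) > 1)
  cls[amb] <- 0L
  conf[amb] <- 1 / ncol(post)
  out <- data.frame(predicted_class = cls, confidence = conf, ambiguous = amb)
  colnames_post <- paste0("p", seq_len(ncol(post)) - 1L)
  out[colnames_post] <- post
  out
}

# softplus parameterization for learnable alpha: alpha = log1p(exp(raw))
alpha_from_raw <- function(raw) log1p(exp(raw))
raw_from_alpha <- function(alpha) log(expm1(alpha))
dalpha_draw <- function(raw) 1 / (1 + exp(-raw))   # d softplus / d raw
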