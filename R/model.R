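#' Multiple-instance attention model
#'
#' Assembles the full bag classifier: a convolutional instance encoder, an
#' instance aggregation operator (tanh-scored attention by default, max or
#' mean pooling as ablations) and a linear-sigmoid bag head.
#'
#' With attention pooling, instance features \eqn{h_i \in R^{512}} receive
#' scores \eqn{s_i = W_2^T \tanh(W_1^T h_i + b_1) + b_2}, the weights are
#' \eqn{a = \mathrm{softmax}(s)} across the bag, and the bag feature is
#' \eqn{M = \sum_i a_i h_i}. \eqn{W_1 \in R^{512\times 128}},
#' \eqn{W_2 \in R^{128\times 1}}, \eqn{b_1 \in R^{128}} and \eqn{b_2} is a
#' scalar (a constant shift that cancels in the softmax). The bag probability
#' is \eqn{\sigma(w^T M + b)}.
#'
#' @param encoder_spec An [encoder_spec()]; default tinycnn.
#' @param pooling `"attention"`, `"max"` or `"mean"`.
#' @param attn_hidden Hidden width of the attention scorer (default 128).
#' @param seed Integer seed for all weight initialization.
#' @return Object of class `mil_model`.
#' @export
mil_model <- function(encoder_spec = sonomil::encoder_spec(),
                      pooling = c("attention", "max", "mean"),
                      attn_hidden = 128L, seed = 1L) {
  pooling <- match.arg(pooling)
  encoder <- build_encoder(encoder_spec, seed = seed)
  d <- encoder_spec$feature_dim
  set.seed(seed + 1L)
  attn <- if (pooling == "attention") attention_params(d, attn_hidden) else NULL
  set.seed(seed + 2L)
  head <- list(w = stats::rnorm(d, sd = 1 / sqrt(d)), b = 0)
  structure(
    list(encoder = encoder, attn = attn, head = head, pooling = pooling,
         attn_hidden = as.integer(attn_hidden), seed = as.integer(seed)),
    class = "mil_model"
  )
}

#' Attention scorer parameters
#'
#' Fresh (small random) parameters for the two-layer tanh attention scorer.
#' Draws from the current RNG state.
#'
#' @param feature_dim Instance feature dimensionality (512).
#' @param hidden Hidden width (128).
#' @return List with `W1` (512 x hidden), `b1` (hidden), `W2` (hidden x 1),
#'   `b2` (scalar), class `attention_params`.
#' @export
attention_params <- function(feature_dim = 512L, hidden = 128L) {
  structure(
    list(
      W1 = matrix(stats::rnorm(feature_dim * hidden, sd = 1 / sqrt(feature_dim)),
                  feature_dim, hidden),
      b1 = numeric(hidden),
      W2 = matrix(stats::rnorm(hidden, sd = 1 / sqrt(hidden)), hidden, 1L),
      b2 = 0
    ),
    class = "attention_params"
  )
}

#' Attention aggregation of instance features
#'
#' Computes softmax-normalized attention weights over a bag's instances and
#' the attention-weighted bag feature. The softmax subtracts the maximum
#' score before exponentiation, so arbitrary finite scores are safe.
#'
#' @param H Numeric matrix N x 512 of instance features.
#' @param params [attention_params()].
#' @return List with `weights` (length N, positive, summing to 1), `M`
#'   (length-512 bag feature) and `scores` (raw instance scores).
#' @export
attention_pool <- function(H, params) {
  check_features(H)
  n <- nrow(H)
  pre <- H %*% params$W1 + rep(params$b1, each = n)
  Tm <- tanh(pre)
  s <- as.vector(Tm %*% params$W2) + params$b2
  z <- exp(s - max(s))
  a <- z / sum(z)
  M <- as.vector(crossprod(H, a))
  list(weights = a, M = M, scores = s, tanh = Tm)
}

#' Max and mean pooling of instance features
#'
#' Element-wise maximum / arithmetic mean over a bag's instance features;
#' the ablation baselines for attention aggregation.
#'
#' @param H Numeric matrix N x 512.
#' @return Length-512 numeric vector.
#' @export
max_pool <- function(H) {
  check_features(H)
  apply(H, 2L, max)
}

#' @rdname max_pool
#' @export
mean_pool <- function(H) {
  check_features(H)
  colMeans(H)
}

check_features <- function(H) {
  if (!is.matrix(H) || nrow(H) < 1L) {
    stop("instance feature matrix must have at least one row (empty bag?)",
         call. = FALSE)
  }
  if (!all(is.finite(H))) stop("non-finite instance features", call. = FALSE)
  invisible(H)
}

#' Bag-level classification from a pooled feature
#'
#' Linear layer plus sigmoid on the aggregated 512-d bag feature.
#'
#' @param M Pooled bag feature (length 512).
#' @param head List with weight vector `w` and scalar bias `b`.
#' @param attention Optional attention weights to attach to the prediction.
#' @return Object of class `bag_prediction`: `probability`, `logits`,
#'   `pooled_feature`, and `attention` (NULL unless attention pooling).
#' @export
classify_bag <- function(M, head, attention = NULL) {
  if (!all(is.finite(M))) stop("non-finite pooled feature", call. = FALSE)
  logits <- sum(head$w * M) + head$b
  structure(
    list(probability = stats::plogis(logits), logits = logits,
         pooled_feature = M, attention = attention),
    class = "bag_prediction"
  )
}

# Full forward pass over one bag; keep_cache retains what the backward pass
# and Grad-CAM need.
forward_bag <- function(model, bag, keep_cache = FALSE) {
  enc <- encoder_forward(model$encoder, bag$images, keep_cache = keep_cache)
  H <- enc$H
  if (model$pooling == "attention") {
    ap <- attention_pool(H, model$attn)
    M <- ap$M
    attention <- ap$weights
  } else if (model$pooling == "max") {
    M <- max_pool(H)
    ap <- NULL
    attention <- NULL
  } else {
    M <- mean_pool(H)
    ap <- NULL
    attention <- NULL
  }
  pred <- classify_bag(M, model$head, attention = attention)
  list(pred = pred, H = H, enc = enc, ap = ap, M = M)
}

# Gradients of `scale * logit` w.r.t. all trainable parameters (and the
# deepest conv maps when want_cam). For BCE training, scale = p - y.
backward_bag <- function(model, fwd, scale, want_cam = FALSE) {
  H <- fwd$H
  n <- nrow(H)
  dlogit <- scale
  gw_head <- dlogit * fwd$M
  gb_head <- dlogit
  dM <- dlogit * model$head$w
  attn_grads <- NULL
  if (model$pooling == "attention") {
    ap <- fwd$ap
    a <- ap$weights
    gA <- as.vector(H %*% dM)              # dL/da_i
    ds <- a * (gA - sum(a * gA))           # through softmax
    dTm <- (ds %*% t(model$attn$W2)) * (1 - ap$tanh^2)
    attn_grads <- list(
      W1 = crossprod(H, dTm),
      b1 = colSums(dTm),
      W2 = crossprod(ap$tanh, ds),
      b2 = sum(ds)
    )
    dH <- outer(a, dM) + dTm %*% t(model$attn$W1)
  } else if (model$pooling == "mean") {
    dH <- matrix(dM, n, length(dM), byrow = TRUE) / n
  } else {  # max: route to argmax rows (ties split evenly)
    mx <- apply(H, 2L, max)
    mask <- H == rep(mx, each = n)
    cnt <- colSums(mask)
    dH <- mask * rep(dM / cnt, each = n)
  }
  eb <- encoder_backward(model$encoder, fwd$enc, dH, want_cam = want_cam)
  list(encoder = eb$grads, attn = attn_grads,
       head = list(w = gw_head, b = gb_head), cam_grad = eb$cam_grad)
}

#' Predict the risk probability of one bag
#'
#' Composition encode -> aggregate -> classify. The probability is invariant
#' to the order of instances within the bag; only the ordering of the
#' attached attention weights follows the input order.
#'
#' @param model A [mil_model()].
#' @param bag A preprocessed [image_bag()].
#' @return A `bag_prediction`.
#' @export
predict_bag <- function(model, bag) {
  stopifnot(inherits(model, "mil_model"))
  forward_bag(model, bag, keep_cache = FALSE)$pred
}

#' @export
print.bag_prediction <- function(x, ...) {
  cat(sprintf("bag prediction: p(high-risk) = %.4f (logit %.4f)\n",
              x$probability, x$logits))
  if (!is.null(x$attention)) {
    cat("attention weights:",
        paste(sprintf("%.3f", x$attention), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
print.mil_model <- function(x, ...) {
  cat(sprintf("MIL model: backbone %s, pooling %s, feature dim %d\n",
              x$encoder$spec$backbone, x$pooling,
              x$encoder$spec$feature_dim))
  invisible(x)
}
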