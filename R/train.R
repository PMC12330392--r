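#' Training configuration
#'
#' Bag-level training recipe: Adam, one patient per optimization step, and
#' binary cross-entropy on the bag probability. The default learning rate
#' (5e-5) and epoch count (100) are the settings used when fine-tuning a
#' pretrained backbone; for the from-scratch tinycnn a larger rate (1e-3,
#' the conventional Adam default) is appropriate — see the package
#' vignette.
#'
#' @param lr Positive learning rate (default 5e-5).
#' @param epochs Positive epoch count (default 100).
#' @param seed Integer seed controlling shuffling (weights are seeded by
#'   the model constructor).
#' @param val_frac Fraction of training bags held out (stratified) for
#'   checkpoint selection when no validation set is supplied; default 0.15.
#' @param early_stop_patience Optional: stop after this many epochs without
#'   validation-AUC improvement (off by default).
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 5e-5, epochs = 100L, seed = 1L,
                         val_frac = 0.15, early_stop_patience = NULL) {
  if (!is.numeric(lr) || lr <= 0) {
    stop("train_config: invalid `lr`: must be > 0", call. = FALSE)
  }
  if (is.na(epochs) || epochs < 1L) {
    stop("train_config: invalid `epochs`: must be >= 1", call. = FALSE)
  }
  if (val_frac < 0 || val_frac >= 1) {
    stop("train_config: invalid `val_frac`: must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(lr = lr, epochs = as.integer(epochs), seed = as.integer(seed),
         val_frac = val_frac,
         early_stop_patience = early_stop_patience,
         optimizer = "adam", loss = "bce", bags_per_step = 1L),
    class = "train_config"
  )
}

#' Binary cross-entropy loss
#'
#' \eqn{-[y \log p + (1-y)\log(1-p)]} with the probability clamped to
#' \eqn{[10^{-7}, 1-10^{-7}]}. Vectorized over inputs.
#'
#' @param probability Predicted probabilities in \[0, 1\].
#' @param label Binary labels.
#' @return Non-negative loss values.
#' @export
bce_loss <- function(probability, label) {
  p <- pmin(pmax(probability, 1e-7), 1 - 1e-7)
  -(label * log(p) + (1 - label) * log(1 - p))
}

# ---- parameter plumbing -----------------------------------------------------

# Flatten the trainable arrays of a model into a named list (views, not
# copies), and write a compatible list back.
model_params <- function(model) {
  p <- list()
  for (i in seq_along(model$encoder$layers)) {
    l <- model$encoder$layers[[i]]
    if (l$op == "conv") {
      p[[paste0("enc", i, ".W")]] <- l$W
      p[[paste0("enc", i, ".b")]] <- l$b
    }
  }
  if (!is.null(model$attn)) {
    p[["attn.W1"]] <- model$attn$W1
    p[["attn.b1"]] <- model$attn$b1
    p[["attn.W2"]] <- model$attn$W2
    p[["attn.b2"]] <- model$attn$b2
  }
  p[["head.w"]] <- model$head$w
  p[["head.b"]] <- model$head$b
  p
}

set_model_params <- function(model, p) {
  for (nm in names(p)) {
    if (startsWith(nm, "enc")) {
      parts <- strsplit(sub("^enc", "", nm), ".", fixed = TRUE)[[1]]
      i <- as.integer(parts[1])
      model$encoder$layers[[i]][[parts[2]]] <- p[[nm]]
    } else if (startsWith(nm, "attn.")) {
      model$attn[[sub("^attn\\.", "", nm)]] <- p[[nm]]
    } else {
      model$head[[sub("^head\\.", "", nm)]] <- p[[nm]]
    }
  }
  model
}

# Gradients from backward_bag(), in model_params() layout.
flatten_grads <- function(model, g) {
  out <- list()
  for (i in seq_along(model$encoder$layers)) {
    if (!is.null(g$encoder[[i]])) {
      out[[paste0("enc", i, ".W")]] <- g$encoder[[i]]$dW
      out[[paste0("enc", i, ".b")]] <- g$encoder[[i]]$db
    }
  }
  if (!is.null(g$attn)) {
    out[["attn.W1"]] <- g$attn$W1
    out[["attn.b1"]] <- g$attn$b1
    out[["attn.W2"]] <- g$attn$W2
    out[["attn.b2"]] <- g$attn$b2
  }
  out[["head.w"]] <- g$head$w
  out[["head.b"]] <- g$head$b
  out
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# ---- training loop ----------------------------------------------------------

#' Train a MIL model on bags
#'
#' End-to-end bag-level training: one Adam step per bag (batch = one
#' patient), binary cross-entropy on the bag probability. Per-epoch history
#' records the mean training loss and validation AUC/accuracy; the
#' checkpoint with the best validation AUC is retained. If `val_bags` is
#' NULL, a stratified `val_frac` of the training bags is held out for
#' checkpointing and the rest is trained on.
#'
#' @param train_bags List of preprocessed [image_bag()] objects containing
#'   both classes.
#' @param model A [mil_model()].
#' @param config A [train_config()].
#' @param val_bags Optional list of preprocessed validation bags.
#' @param verbose Print one line per epoch.
#' @return List of class `mil_fit`: `model` (best-by-validation-AUC),
#'   `final_model`, `history` (data.frame epoch/loss/val_auc/val_accuracy),
#'   `best_epoch`.
#' @export
train_mil <- function(train_bags, model, config = train_config(),
                      val_bags = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "mil_model"), inherits(config, "train_config"))
  labels <- vapply(train_bags, function(b) b$bag_label, integer(1))
  if (length(unique(labels)) < 2L) {
    stop("train_mil: training data must contain both classes", call. = FALSE)
  }
  if (is.null(val_bags) && config$val_frac > 0) {
    sp <- split_by_patient(train_bags, train_frac = 1 - config$val_frac,
                           stratify = TRUE, seed = config$seed + 131L)
    val_bags <- sp$test
    train_bags <- sp$train
  }
  params <- model_params(model)
  state <- adam_init(params)
  n <- length(train_bags)
  hist <- vector("list", config$epochs)
  best_auc <- -Inf
  best_model <- model
  best_epoch <- NA_integer_
  stale <- 0L
  set.seed(config$seed)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(n)
    for (s in seq_len(n)) {
      bag <- train_bags[[ord[s]]]
      fwd <- forward_bag(model, bag, keep_cache = TRUE)
      p <- fwd$pred$probability
      y <- bag$bag_label
      losses[s] <- bce_loss(p, y)
      if (!is.finite(losses[s])) {
        stop("train_mil: divergence (non-finite loss) at epoch ", ep,
             call. = FALSE)
      }
      g <- flatten_grads(model, backward_bag(model, fwd, scale = p - y))
      upd <- adam_step(params, g, state, lr = config$lr)
      params <- upd$params
      state <- upd$state
      model <- set_model_params(model, params)
    }
    val_auc <- NA_real_
    val_acc <- NA_real_
    if (length(val_bags) > 0) {
      vp <- predict_bags(model, val_bags)
      if (length(unique(vp$label)) > 1L) {
        val_auc <- auc_score(vp$label, vp$probability)
      }
      val_acc <- mean((vp$probability >= 0.5) == (vp$label == 1L))
    }
    hist[[ep]] <- data.frame(epoch = ep, loss = mean(losses),
                             val_auc = val_auc, val_accuracy = val_acc)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val_auc %s", ep, mean(losses),
                      ifelse(is.na(val_auc), "NA", sprintf("%.3f", val_auc))))
    }
    track <- if (is.na(val_auc)) -mean(losses) else val_auc
    if (track > best_auc) {
      best_auc <- track
      best_model <- model
      best_epoch <- ep
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (!is.null(config$early_stop_patience) &&
          stale >= config$early_stop_patience) break
    }
  }
  structure(
    list(model = best_model, final_model = model,
         history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]),
         best_epoch = best_epoch),
    class = "mil_fit"
  )
}

#' Predict a set of bags
#'
#' @param model A [mil_model()].
#' @param bags List of preprocessed bags.
#' @return data.frame with columns `patient_id`, `label`, `probability`.
#' @export
predict_bags <- function(model, bags) {
  data.frame(
    patient_id = vapply(bags, function(b) b$patient_id, character(1)),
    label = vapply(bags, function(b) b$bag_label, integer(1)),
    probability = vapply(bags, function(b) predict_bag(model, b)$probability,
                         numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.mil_fit <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("MIL fit: %d epochs, final loss %.4f, best epoch %s\n",
              n, x$history$loss[n],
              ifelse(is.na(x$best_epoch), "-", x$best_epoch)))
  invisible(x)
}
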