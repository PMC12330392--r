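# Independent reference implementations used as oracles. These deliberately
# use naive scalar loops and share no code with the package internals.

# Attention pooling via per-instance scalar arithmetic.
oracle_attention <- function(H, params) {
  n <- nrow(H)
  s <- numeric(n)
  for (i in seq_len(n)) {
    t_i <- numeric(ncol(params$W1))
    for (k in seq_len(ncol(params$W1))) {
      acc <- params$b1[k]
      for (j in seq_len(ncol(H))) acc <- acc + params$W1[j, k] * H[i, j]
      t_i[k] <- tanh(acc)
    }
    s[i] <- sum(params$W2[, 1] * t_i) + params$b2
  }
  e <- exp(s - max(s))
  a <- e / sum(e)
  M <- numeric(ncol(H))
  for (j in seq_len(ncol(H))) M[j] <- sum(a * H[, j])
  list(a = a, M = M)
}

# Element-wise pooling by explicit loops.
oracle_max_pool <- function(H) {
  out <- numeric(ncol(H))
  for (j in seq_len(ncol(H))) {
    m <- H[1, j]
    for (i in seq_len(nrow(H))) if (H[i, j] > m) m <- H[i, j]
    out[j] <- m
  }
  out
}
oracle_mean_pool <- function(H) {
  out <- numeric(ncol(H))
  for (j in seq_len(ncol(H))) out[j] <- sum(H[, j]) / nrow(H)
  out
}

# AUC as the normalized count of correctly ordered positive/negative pairs,
# ties counted one half. O(n^2).
oracle_pairwise_auc <- function(label, score) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Confusion-matrix metrics by exhaustive counting (ties at the cutoff are
# called positive, matching the package's rule).
oracle_confusion <- function(label, prob, threshold) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(label)) {
    pred <- if (prob[i] >= threshold) 1 else 0
    if (pred == 1 && label[i] == 1) tp <- tp + 1
    if (pred == 1 && label[i] == 0) fp <- fp + 1
    if (pred == 0 && label[i] == 1) fn <- fn + 1
    if (pred == 0 && label[i] == 0) tn <- tn + 1
  }
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = (tp + tn) / length(label), precision = prec, recall = rec,
       f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
}

# Naive same-padding 3x3 convolution of a single-channel stack by nested
# loops: `maps` is a list of H x W matrices (channels), `W` the package's
# (9*c_in) x c_out weight layout (row offsets dr-fastest within dc, channels
# outer), `b` the bias vector.
oracle_conv3 <- function(maps, W, b) {
  H <- nrow(maps[[1]]); Wd <- ncol(maps[[1]])
  c_in <- length(maps); c_out <- length(b)
  out <- vector("list", c_out)
  for (co in seq_len(c_out)) {
    acc <- matrix(b[co], H, Wd)
    for (ci in seq_len(c_in)) {
      P <- matrix(0, H + 2, Wd + 2)
      P[2:(H + 1), 2:(Wd + 1)] <- maps[[ci]]
      idx <- 0
      for (dc in -1:1) for (dr in -1:1) {
        idx <- idx + 1
        acc <- acc + W[(ci - 1) * 9 + idx, co] *
          P[(2 + dr):(H + 1 + dr), (2 + dc):(Wd + 1 + dc)]
      }
    }
    out[[co]] <- acc
  }
  out
}

oracle_avgpool2 <- function(maps) {
  lapply(maps, function(m) {
    H2 <- nrow(m) / 2; W2 <- ncol(m) / 2
    out <- matrix(0, H2, W2)
    for (r in seq_len(H2)) for (c in seq_len(W2)) {
      out[r, c] <- mean(m[(2 * r - 1):(2 * r), (2 * c - 1):(2 * c)])
    }
    out
  })
}

# The whole tinycnn feature extractor, layer by layer, using the oracles
# above. `enc` is a built tinycnn encoder; `img` one H x W matrix.
oracle_tinycnn_features <- function(enc, img) {
  maps <- list(img)
  for (l in enc$layers) {
    if (l$op == "avgpool") {
      maps <- oracle_avgpool2(maps)
    } else if (l$op == "conv") {
      maps <- oracle_conv3(maps, l$W, l$b)
    } else if (l$op == "relu") {
      maps <- lapply(maps, function(m) pmax(m, 0))
    }
  }
  vapply(maps, mean, numeric(1))  # adaptive average pooling
}
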