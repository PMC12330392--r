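# Low-level network primitives.
#
# Feature maps are dense matrices of shape (B*H*W) x C: image b occupies the
# contiguous row block ((b-1)*H*W + 1):(b*H*W), within which rows follow the
# column-major vectorization of the H x W plane. All instances of a bag are
# processed as one batch so the heavy lifting is a handful of BLAS gemms.

.nn_cache <- new.env(parent = emptyenv())

.cache_get <- function(key, builder) {
  v <- .nn_cache[[key]]
  if (is.null(v)) {
    v <- builder()
    assign(key, v, envir = .nn_cache)
  }
  v
}

# Spatial gather indices for same-size k x k convolution with zero padding.
# Returns (B*H*W) x k^2 integer matrix of row indices into the padded stack
# (B*Hp*Wp rows). Offset columns are ordered dr-fastest, matching the weight
# row layout used by conv_init().
im2col_idx <- function(B, H, W, k) {
  pad <- (k - 1L) %/% 2L
  key <- paste("i2c", B, H, W, k, sep = "_")
  .cache_get(key, function() {
    Hp <- H + 2L * pad
    Wp <- W + 2L * pad
    rr <- rep.int(seq_len(H), W)
    cc <- rep(seq_len(W), each = H)
    offs <- expand.grid(dr = -pad:pad, dc = -pad:pad)
    idx1 <- matrix(0L, H * W, k * k)
    for (j in seq_len(k * k)) {
      idx1[, j] <- (cc + pad + offs$dc[j] - 1L) * Hp + (rr + pad + offs$dr[j])
    }
    if (B == 1L) return(idx1)
    idx1[rep.int(seq_len(H * W), B), , drop = FALSE] +
      rep((0:(B - 1L)) * (Hp * Wp), each = H * W)
  })
}

# Row indices of the unpadded pixels inside the padded stack.
pad_interior_idx <- function(B, H, W, pad) {
  key <- paste("pint", B, H, W, pad, sep = "_")
  .cache_get(key, function() {
    Hp <- H + 2L * pad
    Wp <- W + 2L * pad
    rr <- rep.int(seq_len(H), W)
    cc <- rep(seq_len(W), each = H)
    i1 <- (cc + pad - 1L) * Hp + (rr + pad)
    if (B == 1L) return(i1)
    rep.int(i1, B) + rep((0:(B - 1L)) * (Hp * Wp), each = H * W)
  })
}

conv_init <- function(c_in, c_out, k = 3L, gain = sqrt(2)) {
  fan_in <- k * k * c_in
  list(
    op    = "conv",
    W     = matrix(stats::rnorm(fan_in * c_out, sd = gain / sqrt(fan_in)),
                   fan_in, c_out),
    b     = numeric(c_out),
    k     = as.integer(k),
    c_in  = as.integer(c_in),
    c_out = as.integer(c_out)
  )
}

conv_forward <- function(layer, x, B, H, W) {
  k <- layer$k
  pad <- (k - 1L) %/% 2L
  c_in <- ncol(x)
  nrP <- B * (H + 2L * pad) * (W + 2L * pad)
  P <- matrix(0, nrP, c_in)
  P[pad_interior_idx(B, H, W, pad), ] <- x
  idx <- im2col_idx(B, H, W, k)
  nidx <- length(idx)
  full <- rep.int(as.vector(idx), c_in) +
    rep((0:(c_in - 1L)) * nrP, each = nidx)
  Xcol <- P[full]
  dim(Xcol) <- c(B * H * W, k * k * c_in)
  out <- Xcol %*% layer$W
  out <- out + rep(layer$b, each = nrow(out))
  list(out = out, Xcol = Xcol)
}

conv_backward <- function(layer, cache, dout, B, H, W, want_dx = TRUE) {
  k <- layer$k
  pad <- (k - 1L) %/% 2L
  c_in <- layer$c_in
  dW <- crossprod(cache$Xcol, dout)
  db <- colSums(dout)
  if (!want_dx) return(list(dW = dW, db = db, dx = NULL))
  dXcol <- tcrossprod(dout, layer$W)
  nrP <- B * (H + 2L * pad) * (W + 2L * pad)
  dP <- matrix(0, nrP, c_in)
  idx <- im2col_idx(B, H, W, k)
  k2 <- k * k
  ch_cols <- (0:(c_in - 1L)) * k2
  for (j in seq_len(k2)) {
    rows <- idx[, j]
    dP[rows, ] <- dP[rows, ] + dXcol[, j + ch_cols, drop = FALSE]
  }
  dx <- dP[pad_interior_idx(B, H, W, pad), , drop = FALSE]
  list(dW = dW, db = db, dx = dx)
}

# 2x2 non-overlapping pooling child indices: four vectors of length B*(H/2)*(W/2)
# into the input stack; (H, W) are the *input* spatial dims.
pool2_idx <- function(B, H, W) {
  key <- paste("p2", B, H, W, sep = "_")
  .cache_get(key, function() {
    H2 <- H %/% 2L
    W2 <- W %/% 2L
    rr <- rep.int(seq_len(H2), W2)
    cc <- rep(seq_len(W2), each = H2)
    lapply(list(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L)), function(d) {
      v <- (2L * (cc - 1L) + d[2] - 1L) * H + (2L * (rr - 1L) + d[1])
      if (B == 1L) v else
        rep.int(v, B) + rep((0:(B - 1L)) * (H * W), each = H2 * W2)
    })
  })
}

avgpool2_forward <- function(x, B, H, W) {
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  i <- pool2_idx(B, H, W)
  (x[i[[1]], , drop = FALSE] + x[i[[2]], , drop = FALSE] +
   x[i[[3]], , drop = FALSE] + x[i[[4]], , drop = FALSE]) * 0.25
}

avgpool2_backward <- function(dout, B, H, W) {
  i <- pool2_idx(B, H, W)
  dx <- matrix(0, B * H * W, ncol(dout))
  g <- dout * 0.25
  for (j in 1:4) dx[i[[j]], ] <- g
  dx
}

maxpool2_forward <- function(x, B, H, W) {
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  i <- pool2_idx(B, H, W)
  ch <- lapply(i, function(ii) x[ii, , drop = FALSE])
  list(out = pmax(ch[[1]], ch[[2]], ch[[3]], ch[[4]]), children = ch)
}

maxpool2_backward <- function(cache, dout, B, H, W) {
  ch <- cache$children
  mx <- pmax(ch[[1]], ch[[2]], ch[[3]], ch[[4]])
  masks <- lapply(ch, function(z) z == mx)
  cnt <- masks[[1]] + masks[[2]] + masks[[3]] + masks[[4]]
  i <- pool2_idx(B, H, W)
  dx <- matrix(0, B * H * W, ncol(dout))
  for (j in 1:4) dx[i[[j]], ] <- dout * masks[[j]] / cnt
  dx
}

relu_forward <- function(x) x * (x > 0)
relu_backward <- function(x_in, dout) dout * (x_in > 0)

# Adaptive spatial pooling of the deepest maps: (B*HW) x C -> B x C.
global_pool_forward <- function(x, B, HW, type = c("avg", "max")) {
  type <- match.arg(type)
  if (type == "avg") {
    grp <- rep(seq_len(B), each = HW)
    rowsum(x, grp, reorder = FALSE) / HW
  } else {
    out <- matrix(0, B, ncol(x))
    for (b in seq_len(B)) {
      blk <- x[((b - 1L) * HW + 1L):(b * HW), , drop = FALSE]
      out[b, ] <- apply(blk, 2L, max)
    }
    out
  }
}

global_avgpool_backward <- function(dH, B, HW) {
  dH[rep(seq_len(B), each = HW), , drop = FALSE] / HW
}
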