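#' Instance encoder specification
#'
#' Describes the convolutional network that maps each instance image to a
#' 512-dimensional feature vector. Two backbones are available:
#' \describe{
#'   \item{`tinycnn`}{A compact 3-block CNN (8, 16, 512 channels) trained from
#'     scratch. Runs comfortably on a single CPU and is the default for
#'     synthetic experiments. Requires input sides divisible by 8.}
#'   \item{`vgg13`}{The 10-convolution VGG13 feature stack (3-channel input,
#'     max pooling, sides divisible by 32). Pretrained ImageNet weights cannot
#'     be distributed with this package, so `pretrained = TRUE` raises a
#'     capability error; `pretrained = FALSE` gives a randomly initialized
#'     VGG13 of the same shape.}
#' }
#' Whatever the input resolution, the deepest feature maps are spatially
#' pooled (adaptive average by default, max optional) to one 512-vector per
#' instance, so bags of any image size yield an N x 512 feature matrix.
#'
#' @param backbone `"tinycnn"` or `"vgg13"`.
#' @param pretrained Logical; only meaningful for `vgg13` (see above).
#' @param feature_dim Output dimensionality; fixed at 512.
#' @param pool Spatial pooling of the deepest feature map: `"avg"` or `"max"`.
#' @return An object of class `encoder_spec`.
#' @export
encoder_spec <- function(backbone = c("tinycnn", "vgg13"), pretrained = FALSE,
                         feature_dim = 512L, pool = c("avg", "max")) {
  backbone <- match.arg(backbone)
  pool <- match.arg(pool)
  if (!identical(as.integer(feature_dim), 512L)) {
    stop("encoder_spec: feature_dim is fixed at 512", call. = FALSE)
  }
  structure(
    list(backbone = backbone, pretrained = isTRUE(pretrained),
         feature_dim = 512L, pool = pool),
    class = "encoder_spec"
  )
}

#' Build an instance encoder from a specification
#'
#' @param spec An [encoder_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `sonomil_encoder` holding the layer stack.
#' @export
build_encoder <- function(spec = encoder_spec(), seed = 1L) {
  stopifnot(inherits(spec, "encoder_spec"))
  if (spec$backbone == "vgg13" && spec$pretrained) {
    stop("build_encoder: pretrained VGG13 weights are not available in this ",
         "installation (they cannot be shipped with the package); use ",
         "backbone = \"tinycnn\" or pretrained = FALSE", call. = FALSE)
  }
  set.seed(seed)
  if (spec$backbone == "tinycnn") {
    # stem pool halves the input before the first convolution (cheap
    # anti-aliased downsampling); three conv blocks then reach 512 channels
    layers <- list(
      list(op = "avgpool"),
      conv_init(1L, 8L),  list(op = "relu"), list(op = "avgpool"),
      conv_init(8L, 16L), list(op = "relu"), list(op = "avgpool"),
      conv_init(16L, 512L), list(op = "relu")
    )
    in_channels <- 1L
    min_div <- 8L
  } else {
    widths <- list(c(3L, 64L), c(64L, 64L), c(64L, 128L), c(128L, 128L),
                   c(128L, 256L), c(256L, 256L), c(256L, 512L), c(512L, 512L),
                   c(512L, 512L), c(512L, 512L))
    pool_after <- c(2L, 4L, 6L, 8L, 10L)
    layers <- list()
    for (i in seq_along(widths)) {
      layers <- c(layers, list(conv_init(widths[[i]][1], widths[[i]][2]),
                               list(op = "relu")))
      if (i %in% pool_after) layers <- c(layers, list(list(op = "maxpool")))
    }
    in_channels <- 3L
    min_div <- 32L
  }
  structure(
    list(layers = layers, in_channels = in_channels, min_div = min_div,
         spec = spec),
    class = "sonomil_encoder"
  )
}

# Stack a bag's images into the (N*H*W) x C batch matrix, replicating
# grayscale to the encoder's channel count when needed.
stack_images <- function(images, in_channels) {
  if (length(images) == 0L) stop("empty bag: no images to encode", call. = FALSE)
  d <- dim(images[[1]])
  for (im in images) {
    if (is.null(dim(im)) || length(dim(im)) != 2L) {
      stop("encode_instances: images must be 2-D matrices", call. = FALSE)
    }
    if (!identical(dim(im), d)) {
      stop("encode_instances: all images in a bag must share one size",
           call. = FALSE)
    }
  }
  v <- unlist(images, use.names = FALSE)
  x <- matrix(v, ncol = 1L)
  if (in_channels > 1L) x <- x[, rep(1L, in_channels), drop = FALSE]
  list(x = x, N = length(images), H = d[1], W = d[2])
}

# Run the layer stack. Returns the N x 512 feature matrix plus (optionally)
# the per-layer caches needed for the backward pass and Grad-CAM, and the
# deepest post-activation conv maps.
encoder_forward <- function(encoder, images, keep_cache = FALSE) {
  st <- stack_images(images, encoder$in_channels)
  x <- st$x; B <- st$N; H <- st$H; W <- st$W
  if (H %% encoder$min_div != 0L || W %% encoder$min_div != 0L) {
    stop("encoder input sides must be divisible by ", encoder$min_div,
         " (got ", H, "x", W, ")", call. = FALSE)
  }
  layers <- encoder$layers
  n <- length(layers)
  conv_idx <- which(vapply(layers, function(l) l$op == "conv", logical(1)))
  last_conv <- max(conv_idx)
  cam_idx <- if (last_conv < n && layers[[last_conv + 1L]]$op == "relu")
    last_conv + 1L else last_conv

  caches <- if (keep_cache) vector("list", n) else NULL
  dims <- vector("list", n)  # input dims per layer
  cam <- NULL
  for (i in seq_len(n)) {
    l <- layers[[i]]
    dims[[i]] <- c(B = B, H = H, W = W)
    if (l$op == "conv") {
      cf <- conv_forward(l, x, B, H, W)
      if (keep_cache) caches[[i]] <- list(Xcol = cf$Xcol)
      x <- cf$out
    } else if (l$op == "relu") {
      if (keep_cache) caches[[i]] <- list(x_in = x)
      x <- relu_forward(x)
    } else if (l$op == "avgpool") {
      x <- avgpool2_forward(x, B, H, W)
      H <- H %/% 2L; W <- W %/% 2L
    } else if (l$op == "maxpool") {
      mf <- maxpool2_forward(x, B, H, W)
      if (keep_cache) caches[[i]] <- list(children = mf$children)
      x <- mf$out
      H <- H %/% 2L; W <- W %/% 2L
    } else {
      stop("unknown layer op: ", l$op)
    }
    if (i == cam_idx) cam <- list(A = x, H = H, W = W)
  }
  Hmat <- global_pool_forward(x, B, H * W, type = encoder$spec$pool)
  list(H = Hmat, caches = caches, dims = dims, B = B,
       final_H = H, final_W = W, cam_idx = cam_idx, cam = cam)
}

# Backpropagate dH (N x 512) through the encoder. Returns per-conv-layer
# weight gradients and, when `want_cam`, the gradient of the objective with
# respect to the deepest post-activation conv maps.
encoder_backward <- function(encoder, fwd, dH, want_cam = FALSE) {
  if (encoder$spec$pool != "avg") {
    stop("encoder_backward supports the adaptive average pooling head",
         call. = FALSE)
  }
  layers <- encoder$layers
  n <- length(layers)
  g <- global_avgpool_backward(dH, fwd$B, fwd$final_H * fwd$final_W)
  grads <- vector("list", n)
  cam_grad <- NULL
  lowest_conv <- min(which(vapply(layers, function(l) l$op == "conv",
                                  logical(1))))
  for (i in rev(seq_len(n))) {
    if (want_cam && i == fwd$cam_idx) cam_grad <- g
    l <- layers[[i]]
    d <- fwd$dims[[i]]
    if (l$op == "conv") {
      want_dx <- i > lowest_conv
      cb <- conv_backward(l, fwd$caches[[i]], g, d["B"], d["H"], d["W"],
                          want_dx = want_dx)
      grads[[i]] <- list(dW = cb$dW, db = cb$db)
      if (!want_dx) break
      g <- cb$dx
    } else if (l$op == "relu") {
      g <- relu_backward(fwd$caches[[i]]$x_in, g)
    } else if (l$op == "avgpool") {
      g <- avgpool2_backward(g, d["B"], d["H"], d["W"])
    } else if (l$op == "maxpool") {
      g <- maxpool2_backward(fwd$caches[[i]], g, d["B"], d["H"], d["W"])
    }
  }
  list(grads = grads, cam_grad = cam_grad, dx = g)
}

#' Encode a bag's images into instance features
#'
#' Applies the convolutional backbone to every image of a (preprocessed) bag
#' and spatially pools the deepest feature maps, yielding one 512-dimensional
#' row per instance.
#'
#' @param bag An [image_bag()] whose images are all the same size.
#' @param encoder A built encoder from [build_encoder()].
#' @return A numeric matrix of shape N x 512.
#' @export
encode_instances <- function(bag, encoder) {
  stopifnot(inherits(encoder, "sonomil_encoder"))
  encoder_forward(encoder, bag$images, keep_cache = FALSE)$H
}
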