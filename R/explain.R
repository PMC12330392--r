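#' Grad-CAM saliency for one instance
#'
#' Gradient-weighted class activation mapping on the deepest convolutional
#' layer of the encoder, targeting the bag logit: channel weights are the
#' spatial means of the gradient of the bag logit with respect to the
#' deepest (post-activation) feature maps of the chosen instance; the map is
#' the ReLU of the weighted activation sum, max-normalized to \[0, 1\] and
#' bilinearly upsampled to the instance-image size. This saliency map is
#' distinct from the bag-level attention weights: attention ranks whole
#' images, Grad-CAM localizes evidence within one image.
#'
#' Two gradient targets are available. `target = "bag"` differentiates the
#' logit of the full bag, so the map for instance i is coupled to the whole
#' bag through the attention softmax; when attention is saturated on another
#' image, the gradient reaching a low-weight instance reverses sign (its
#' evidence sits below the bag average) and the ReLU suppresses exactly the
#' lesion — a known failure mode of bag-coupled CAMs in attention MIL.
#' `target = "instance"` (the default for per-image explanation) therefore
#' explains the image as its own singleton bag: the identical Grad-CAM
#' computation on the bag containing only that image, whose logit is the
#' model's evidence for the image itself, free of cross-instance softmax
#' coupling. Use attention weights to rank images, Grad-CAM to localize
#' within them.
#'
#' If the ReLU kills everything (all-zero map), a flat zero map is returned
#' with attribute `flat = TRUE` and a warning.
#'
#' @param model A [mil_model()].
#' @param bag A preprocessed [image_bag()] (no augmentation).
#' @param instance_index Which image of the bag to explain.
#' @param target `"instance"` (singleton-bag evidence map) or `"bag"`
#'   (gradient of the full-bag logit); see Details.
#' @param upsample Return the map at image resolution (default) or at the
#'   feature-map resolution.
#' @return Object of class `heatmap`: list with `values` (matrix in
#'   \[0, 1\]), `raw` (un-normalized weighted sum at feature resolution),
#'   `instance_index`, `target` (the bag logit), `flat`.
#' @export
grad_cam <- function(model, bag, instance_index = 1L,
                     target = c("instance", "bag"), upsample = TRUE) {
  stopifnot(inherits(model, "mil_model"))
  target <- match.arg(target)
  N <- length(bag$images)
  if (instance_index < 1L || instance_index > N) {
    stop("grad_cam: instance_index out of range", call. = FALSE)
  }
  orig_index <- instance_index
  if (target == "instance" && N > 1L) {
    bag <- image_bag(bag$patient_id, bag$images[instance_index],
                     bag$bag_label)
    instance_index <- 1L
  }
  fwd <- forward_bag(model, bag, keep_cache = TRUE)
  bk <- backward_bag(model, fwd, scale = 1, want_cam = TRUE)
  cam <- fwd$enc$cam
  hw <- cam$H * cam$W
  rows <- ((instance_index - 1L) * hw + 1L):(instance_index * hw)
  A <- cam$A[rows, , drop = FALSE]          # hw x C activations
  G <- bk$cam_grad[rows, , drop = FALSE]    # d logit / d A
  alpha <- colMeans(G)                      # spatial mean per channel
  raw <- matrix(pmax(as.vector(A %*% alpha), 0), cam$H, cam$W)
  flat <- max(raw) <= 0
  if (flat) {
    warning("grad_cam: all-zero saliency (gradient dead); returning flat map")
    values <- matrix(0, cam$H, cam$W)
  } else {
    values <- raw / max(raw)
  }
  if (upsample) {
    d <- dim(bag$images[[instance_index]])
    values <- resize_bilinear(values, d[1], d[2])
    values <- pmin(pmax(values, 0), 1)
  }
  structure(
    list(values = values, raw = raw, instance_index = orig_index,
         target = fwd$pred$logits, target_kind = target, flat = flat),
    class = "heatmap"
  )
}

#' Rank a bag's instances by attention weight
#'
#' @param prediction A `bag_prediction` produced with attention pooling.
#' @param top_k How many instances to flag as key (default 3, capped at
#'   bag size).
#' @return Object of class `attention_report`: data.frame with `index`,
#'   `weight`, `rank` (descending weight, ties broken by instance index),
#'   plus attribute `key_instances`.
#' @export
attention_report <- function(prediction, top_k = 3L) {
  stopifnot(inherits(prediction, "bag_prediction"))
  if (is.null(prediction$attention)) {
    stop("attention_report: prediction was not made with attention pooling",
         call. = FALSE)
  }
  w <- prediction$attention
  n <- length(w)
  ord <- order(-w, seq_len(n))   # deterministic tie-break by index
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  rep <- data.frame(index = seq_len(n), weight = w, rank = rank)
  k <- min(as.integer(top_k), n)
  structure(rep, class = c("attention_report", "data.frame"),
            key_instances = ord[seq_len(k)])
}

#' Render a warm-colormap saliency overlay
#'
#' Alpha-blends a heatmap over the grayscale image with a warm (black-red-
#' yellow-white) colormap; blend weight grows with heat, so zero-heat
#' regions stay pure grayscale. Pure visualization — no numeric claims.
#'
#' @param image Grayscale matrix in \[0, 1\].
#' @param heatmap A [grad_cam()] result or a matrix in \[0, 1\] with the
#'   image's dimensions.
#' @param path Output PNG path.
#' @param alpha Maximum blend weight (at heat 1).
#' @return `path`, invisibly.
#' @export
render_overlay <- function(image, heatmap, path, alpha = 0.5) {
  h <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  if (!identical(dim(image), dim(h))) {
    stop("render_overlay: image and heatmap dimensions differ", call. = FALSE)
  }
  ramp <- grDevices::colorRamp(c("black", "red", "yellow", "white"))
  warm <- ramp(as.vector(h)) / 255
  w <- alpha * as.vector(h)
  g <- as.vector(pmin(pmax(image, 0), 1))
  rgb <- array(0, c(nrow(image), ncol(image), 3))
  for (ch in 1:3) {
    rgb[, , ch] <- matrix((1 - w) * g + w * warm[, ch], nrow(image))
  }
  png::writePNG(rgb, target = path)
  invisible(path)
}

#' @export
print.heatmap <- function(x, ...) {
  cat(sprintf("Grad-CAM heatmap: instance %d, %dx%d, target logit %.4f%s\n",
              x$instance_index, nrow(x$values), ncol(x$values), x$target,
              if (x$flat) " (flat: dead gradient)" else ""))
  invisible(x)
}
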