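#' Preprocessing and augmentation specification
#'
#' Controls the uniform preprocessing applied to every image before
#' encoding: resize to a square `target_size`, optional stochastic
#' augmentation (horizontal flip, contrast jitter, rotation, scaling,
#' translation, drawn independently per image), then per-channel
#' normalization `(x - mean) / sd`. With `augment = FALSE` the pipeline is
#' fully deterministic.
#'
#' Augmentation magnitudes default to conventional mild ranges: flip
#' probability 0.5, contrast jitter up to 20%, rotation up to 15 degrees,
#' scale in \[0.9, 1.1\], translation up to 10% of the side.
#'
#' @param target_size Output side in pixels (>= 8). The tinycnn encoder
#'   needs a multiple of 8; 64 is the desk-scale default, 512 mirrors
#'   full-resolution frames.
#' @param augment Logical; enable stochastic augmentation.
#' @param hflip_prob Probability of a horizontal flip, in \[0, 1\].
#' @param contrast_jitter Maximum fractional contrast change, >= 0.
#' @param rotate_deg Maximum absolute rotation, degrees.
#' @param scale_range Multiplicative scale pair (min, max), both > 0.
#' @param translate_frac Maximum fractional shift of the side, in \[0, 1\].
#' @param normalize_mean,normalize_sd Normalization constants. Defaults
#'   (0.5, 0.25) suit the simulator's intensity range; use dataset moments
#'   or ImageNet statistics as appropriate for other data.
#' @return Object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(target_size = 64L, augment = FALSE,
                            hflip_prob = 0.5, contrast_jitter = 0.2,
                            rotate_deg = 15, scale_range = c(0.9, 1.1),
                            translate_frac = 0.1,
                            normalize_mean = 0.5, normalize_sd = 0.25) {
  bad <- function(field, msg) {
    stop("preprocess_spec: invalid `", field, "`: ", msg, call. = FALSE)
  }
  if (is.na(target_size) || target_size < 8L) bad("target_size", "must be >= 8")
  if (hflip_prob < 0 || hflip_prob > 1) bad("hflip_prob", "must lie in [0, 1]")
  if (contrast_jitter < 0) bad("contrast_jitter", "must be >= 0")
  if (rotate_deg < 0) bad("rotate_deg", "must be >= 0")
  if (length(scale_range) != 2L || any(scale_range <= 0) ||
      scale_range[1] > scale_range[2]) {
    bad("scale_range", "need 0 < min <= max")
  }
  if (translate_frac < 0 || translate_frac > 1) {
    bad("translate_frac", "must lie in [0, 1]")
  }
  if (normalize_sd <= 0) bad("normalize_sd", "must be > 0")
  structure(
    list(target_size = as.integer(target_size), augment = isTRUE(augment),
         hflip_prob = hflip_prob, contrast_jitter = contrast_jitter,
         rotate_deg = rotate_deg, scale_range = scale_range,
         translate_frac = translate_frac,
         normalize_mean = normalize_mean, normalize_sd = normalize_sd),
    class = "preprocess_spec"
  )
}

# Bilinear sampling of `img` at fractional (row, col) coordinates; points
# outside the image read the background value.
bilinear_sample <- function(img, r, c, bg = 0) {
  H <- nrow(img)
  W <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0;   fc <- c - c0
  gv <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v <- rep(bg, length(ri))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  v00 <- gv(r0, c0);     v10 <- gv(r0 + 1, c0)
  v01 <- gv(r0, c0 + 1); v11 <- gv(r0 + 1, c0 + 1)
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

#' Bilinear image resize
#'
#' @param img Numeric matrix.
#' @param out_h,out_w Output dimensions.
#' @return Resized matrix.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  H <- nrow(img)
  W <- ncol(img)
  if (H == out_h && W == out_w) return(img)
  rr <- (seq_len(out_h) - 0.5) * H / out_h + 0.5
  cc <- (seq_len(out_w) - 0.5) * W / out_w + 0.5
  r <- rep.int(rr, out_w)
  c <- rep(cc, each = out_h)
  matrix(bilinear_sample(img, pmin(pmax(r, 1), H), pmin(pmax(c, 1), W)),
         out_h, out_w)
}

# Inverse-mapped affine warp about the image center: rotate by `deg`, scale
# by `s`, then translate by (tr, tc) pixels. Bilinear, background 0.
affine_warp <- function(img, deg = 0, s = 1, tr = 0, tc = 0) {
  if (deg == 0 && s == 1 && tr == 0 && tc == 0) return(img)
  H <- nrow(img)
  W <- ncol(img)
  th <- deg * pi / 180
  cy <- (H + 1) / 2
  cx <- (W + 1) / 2
  r <- rep.int(seq_len(H), W) - cy - tr
  c <- rep(seq_len(W), each = H) - cx - tc
  # inverse of rotation(th) * scale(s)
  ri <- ( cos(th) * r + sin(th) * c) / s + cy
  ci <- (-sin(th) * r + cos(th) * c) / s + cx
  matrix(bilinear_sample(img, ri, ci), H, W)
}

#' Preprocess one bag
#'
#' Applies (in order) optional augmentation on the raw intensities, resize
#' to `target_size`, and normalization. Augmentation draws come from the
#' seeded RNG, one independent set per image, so the result is a
#' deterministic function of `(bag, spec, rng_seed)`. Bag label and
#' instance count are never altered.
#'
#' @param bag An [image_bag()].
#' @param spec A [preprocess_spec()].
#' @param rng_seed Integer seed for the augmentation draws.
#' @return A new `image_bag` with transformed images.
#' @export
preprocess <- function(bag, spec, rng_seed = 1L) {
  stopifnot(inherits(bag, "image_bag"), inherits(spec, "preprocess_spec"))
  set.seed(rng_seed)
  out <- vector("list", length(bag$images))
  for (j in seq_along(bag$images)) {
    img <- bag$images[[j]]
    if (is.null(dim(img)) || length(dim(img)) != 2L || any(dim(img) < 1L)) {
      stop("preprocess: image ", j, " is not a non-empty 2-D matrix",
           call. = FALSE)
    }
    if (spec$augment) {
      u_flip <- stats::runif(1)
      cjit <- stats::runif(1, -spec$contrast_jitter, spec$contrast_jitter)
      deg <- stats::runif(1, -spec$rotate_deg, spec$rotate_deg)
      s <- stats::runif(1, spec$scale_range[1], spec$scale_range[2])
      tr <- stats::runif(1, -spec$translate_frac, spec$translate_frac) * nrow(img)
      tc <- stats::runif(1, -spec$translate_frac, spec$translate_frac) * ncol(img)
      if (u_flip < spec$hflip_prob) img <- img[, ncol(img):1, drop = FALSE]
      if (spec$contrast_jitter > 0) {
        m <- mean(img)
        img <- pmin(pmax(m + (1 + cjit) * (img - m), 0), 1)
      }
      img <- affine_warp(img, deg, s, tr, tc)
    }
    img <- resize_bilinear(img, spec$target_size, spec$target_size)
    out[[j]] <- (img - spec$normalize_mean) / spec$normalize_sd
  }
  image_bag(bag$patient_id, out, bag$bag_label,
            instance_labels = bag$instance_labels,
            lesion_masks = bag$lesion_masks)
}

#' Preprocess a list of bags
#'
#' Convenience wrapper: each bag gets a distinct sub-seed derived from
#' `rng_seed` by counter.
#'
#' @inheritParams preprocess
#' @param bags List of [image_bag()] objects.
#' @return List of preprocessed bags.
#' @export
preprocess_bags <- function(bags, spec, rng_seed = 1L) {
  lapply(seq_along(bags), function(i) {
    preprocess(bags[[i]], spec, rng_seed = rng_seed + i)
  })
}

#' Load bags from a manifest
#'
#' Reads a `patient_id,label,image_path` manifest CSV and assembles one
#' [image_bag()] per distinct patient, images in manifest row order.
#' Relative image paths are resolved against the manifest's directory.
#' RGB images are converted to grayscale by channel averaging.
#'
#' @param manifest Path to the manifest CSV.
#' @return List of [image_bag()] objects (order of first appearance).
#' @export
load_bags <- function(manifest) {
  if (!file.exists(manifest)) {
    stop("load_bags: manifest not found: ", manifest, call. = FALSE)
  }
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("patient_id", "label", "image_path")
  if (!all(need %in% names(df))) {
    stop("load_bags: manifest must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  root <- dirname(manifest)
  ids <- unique(df$patient_id)
  bags <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- df[df$patient_id == ids[i], , drop = FALSE]
    labs <- unique(rows$label)
    if (length(labs) != 1L) {
      stop("load_bags: conflicting labels for patient ", ids[i], call. = FALSE)
    }
    imgs <- vector("list", nrow(rows))
    for (j in seq_len(nrow(rows))) {
      p <- rows$image_path[j]
      if (!file.exists(p)) p <- file.path(root, rows$image_path[j])
      if (!file.exists(p)) {
        stop("load_bags: cannot read image file ", rows$image_path[j],
             call. = FALSE)
      }
      im <- png::readPNG(p)
      if (length(dim(im)) == 3L) im <- apply(im[, , 1:3, drop = FALSE], c(1, 2), mean)
      imgs[[j]] <- im
    }
    bags[[i]] <- image_bag(ids[i], imgs, labs)
  }
  bags
}

#' Patient-level train/test split
#'
#' Splits a list of bags at the patient level, so no patient's images can
#' appear on both sides. With `stratify = TRUE` the class proportions of
#' each partition match the full set within rounding.
#'
#' @param bags List of [image_bag()] objects.
#' @param train_frac Fraction of bags assigned to training, in (0, 1);
#'   0.75 gives the conventional 3:1 split.
#' @param stratify Logical; stratify by bag label.
#' @param seed Integer seed for the random assignment.
#' @return List with elements `train` and `test` (both non-empty).
#' @export
split_by_patient <- function(bags, train_frac = 0.75, stratify = TRUE,
                             seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) {
    stop("split_by_patient: train_frac must lie in (0, 1)", call. = FALSE)
  }
  n <- length(bags)
  labels <- vapply(bags, function(b) b$bag_label, integer(1))
  set.seed(seed)
  if (stratify) {
    if (any(table(factor(labels, levels = c(0L, 1L))) < 2L)) {
      stop("split_by_patient: each class needs at least 2 bags to stratify",
           call. = FALSE)
    }
    # per-class floor allocation, remainders to the classes with the
    # largest fractional part so the overall count is round(train_frac * n)
    classes <- sort(unique(labels))
    n_cl <- vapply(classes, function(cl) sum(labels == cl), integer(1))
    k_cl <- floor(train_frac * n_cl)
    short <- round(train_frac * n) - sum(k_cl)
    if (short > 0) {
      give <- order(train_frac * n_cl - k_cl, decreasing = TRUE)
      k_cl[give[seq_len(short)]] <- k_cl[give[seq_len(short)]] + 1L
    }
    k_cl <- pmin(pmax(k_cl, 1L), n_cl - 1L)
    train_idx <- integer(0)
    for (ci in seq_along(classes)) {
      idx <- which(labels == classes[ci])
      train_idx <- c(train_idx, sample(idx, k_cl[ci]))
    }
  } else {
    k <- round(train_frac * n)
    if (k < 1L || k >= n) {
      stop("split_by_patient: split would leave an empty partition",
           call. = FALSE)
    }
    train_idx <- sample.int(n, k)
  }
  train_idx <- sort(train_idx)
  list(train = bags[train_idx], test = bags[setdiff(seq_len(n), train_idx)])
}
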