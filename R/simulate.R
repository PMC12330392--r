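#' Simulator configuration
#'
#' Parameters of the procedural bag generator. Bags obey the standard
#' multiple-instance assumption: a bag is positive iff it contains at least
#' one positive instance, and every instance of a negative bag is negative.
#' Negative instances show a regular, homogeneous, low-contrast ellipse on a
#' speckled background (a benign-looking nodule); positive instances add an
#' irregular-margin lesion at `lesion_contrast` above the background with a
#' handful of bright punctate spots (microcalcification-like).
#'
#' @param n_bags Number of bags (patients) to generate.
#' @param bag_size_range Inclusive integer pair (min, max) of images per bag;
#'   min >= 1. Defaults to (4, 12), giving a mean of about 8 frames per
#'   examination.
#' @param witness_rate Fraction in (0, 1] of instances that are positive
#'   within a positive bag (at least one is always positive).
#' @param image_size Pixels per (square) side. 64 by default; 512 mirrors
#'   full-resolution ultrasound frames.
#' @param lesion_contrast Mean intensity offset of the positive lesion above
#'   background, in \[0, 1\].
#' @param speckle_sd Standard deviation of the additive Gaussian speckle
#'   (clipped to \[0, 1\]); >= 0.
#' @param seed Integer RNG seed; identical config + seed reproduces the
#'   dataset bit for bit.
#' @param class_balance Fraction of positive bags in (0, 1).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_bags = 100L, bag_size_range = c(4L, 12L),
                       witness_rate = 0.5, image_size = 64L,
                       lesion_contrast = 0.5, speckle_sd = 0.05,
                       seed = 1L, class_balance = 0.5) {
  cfg <- list(
    n_bags = as.integer(n_bags), bag_size_range = as.integer(bag_size_range),
    witness_rate = witness_rate, image_size = as.integer(image_size),
    lesion_contrast = lesion_contrast, speckle_sd = speckle_sd,
    seed = as.integer(seed), class_balance = class_balance
  )
  bad <- function(field, msg) {
    stop("sim_config: invalid `", field, "`: ", msg, call. = FALSE)
  }
  if (is.na(cfg$n_bags) || cfg$n_bags < 1L) bad("n_bags", "must be a positive count")
  if (length(cfg$bag_size_range) != 2L || anyNA(cfg$bag_size_range) ||
      cfg$bag_size_range[1] < 1L ||
      cfg$bag_size_range[1] > cfg$bag_size_range[2]) {
    bad("bag_size_range", "need integer pair with 1 <= min <= max")
  }
  if (!is.numeric(cfg$witness_rate) || cfg$witness_rate <= 0 ||
      cfg$witness_rate > 1) bad("witness_rate", "must lie in (0, 1]")
  if (is.na(cfg$image_size) || cfg$image_size < 16L) {
    bad("image_size", "must be at least 16 pixels")
  }
  if (!is.numeric(cfg$lesion_contrast) || cfg$lesion_contrast < 0 ||
      cfg$lesion_contrast > 1) bad("lesion_contrast", "must lie in [0, 1]")
  if (!is.numeric(cfg$speckle_sd) || cfg$speckle_sd < 0) {
    bad("speckle_sd", "must be >= 0")
  }
  if (is.na(cfg$seed)) bad("seed", "must be an integer")
  if (!is.numeric(cfg$class_balance) || cfg$class_balance <= 0 ||
      cfg$class_balance >= 1) bad("class_balance", "must lie in (0, 1)")
  structure(cfg, class = "sim_config")
}

#' One patient's bag of images
#'
#' @param patient_id Character id.
#' @param images List of N >= 1 single-channel matrices with values in
#'   \[0, 1\] (after preprocessing, values may leave that range).
#' @param bag_label 0 (low-risk) or 1 (high-risk) — the only supervision.
#' @param instance_labels Optional per-image 0/1 flags; simulation-only
#'   ground truth, never used for training.
#' @param lesion_masks Optional list of logical matrices marking the lesion
#'   region of each image (simulation-only, for saliency evaluation).
#' @return Object of class `image_bag`.
#' @export
image_bag <- function(patient_id, images, bag_label, instance_labels = NULL,
                      lesion_masks = NULL) {
  if (length(images) < 1L) stop("image_bag: need at least one image", call. = FALSE)
  bag_label <- as.integer(bag_label)
  stopifnot(bag_label %in% c(0L, 1L))
  if (!is.null(instance_labels)) {
    instance_labels <- as.integer(instance_labels)
    stopifnot(length(instance_labels) == length(images))
    if (bag_label == 1L && !any(instance_labels == 1L)) {
      stop("image_bag: positive bag must contain a positive instance",
           call. = FALSE)
    }
    if (bag_label == 0L && any(instance_labels == 1L)) {
      stop("image_bag: negative bag cannot contain positive instances",
           call. = FALSE)
    }
  }
  structure(
    list(patient_id = as.character(patient_id), images = images,
         bag_label = bag_label, instance_labels = instance_labels,
         lesion_masks = lesion_masks),
    class = "image_bag"
  )
}

#' @export
print.image_bag <- function(x, ...) {
  cat(sprintf("image_bag %s: %d images %dx%d, label %d\n", x$patient_id,
              length(x$images), nrow(x$images[[1]]), ncol(x$images[[1]]),
              x$bag_label))
  invisible(x)
}

# Elliptical lesion mask, optionally with an irregular (harmonically
# perturbed) margin. Grids are pixel-centered, coordinates in pixels.
lesion_mask <- function(size, cx, cy, a, b, theta, irregular = FALSE) {
  xs <- matrix(rep(seq_len(size), each = size), size)  # column index
  ys <- matrix(rep(seq_len(size), size), size)         # row index
  dx <- xs - cx
  dy <- ys - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  r2 <- (u / a)^2 + (v / b)^2
  if (!irregular) return(r2 <= 1)
  phi <- atan2(v / b, u / a)
  harm <- stats::runif(3, 0.05, 0.12)
  phase <- stats::runif(3, 0, 2 * pi)
  boundary <- 1 + harm[1] * sin(3 * phi + phase[1]) +
    harm[2] * sin(4 * phi + phase[2]) + harm[3] * sin(5 * phi + phase[3])
  sqrt(r2) <= boundary
}

# Render one instance image. Draws from the current RNG stream.
render_instance <- function(size, positive, lesion_contrast, speckle_sd) {
  bg <- 0.35
  img <- matrix(bg, size, size)
  cx <- stats::runif(1, 0.35, 0.65) * size
  cy <- stats::runif(1, 0.35, 0.65) * size
  a <- stats::runif(1, 0.12, 0.22) * size
  b <- stats::runif(1, 0.12, 0.22) * size
  theta <- stats::runif(1, 0, pi)
  if (positive) {
    mask <- lesion_mask(size, cx, cy, a, b, theta, irregular = TRUE)
    img[mask] <- bg + lesion_contrast
    # bright punctate spots inside the lesion; their brightness scales with
    # the contrast dial so conspicuity has a single control
    spot_val <- min(1, bg + lesion_contrast + 0.3)
    inside <- which(mask)
    n_spots <- sample(3:8, 1L)
    spots <- inside[sample.int(length(inside), min(n_spots, length(inside)))]
    for (s in spots) {
      r <- (s - 1L) %% size + 1L
      c <- (s - 1L) %/% size + 1L
      w <- sample(1:2, 1L)
      rs <- r:min(r + w - 1L, size)
      cs <- c:min(c + w - 1L, size)
      img[rs, cs] <- spot_val
    }
  } else {
    mask <- lesion_mask(size, cx, cy, a, b, theta, irregular = FALSE)
    img[mask] <- bg - 0.12  # regular, homogeneous, mildly hypoechoic
  }
  if (speckle_sd > 0) {
    img <- img + matrix(stats::rnorm(size * size, sd = speckle_sd), size)
  }
  img <- pmin(pmax(img, 0), 1)
  attr(img, "lesion_mask") <- mask
  img
}

#' Generate a synthetic bag dataset
#'
#' Draws `n_bags` bags under [sim_config()]. Exactly
#' `round(n_bags * class_balance)` bags are positive; a positive bag of size
#' N contains `max(1, round(witness_rate * N))` positive instances. Bag
#' labels and sizes are drawn first from the seeded stream; each bag's
#' images are then rendered under a per-bag sub-seed derived by counter, so
#' the dataset is bit-reproducible.
#'
#' @param config A [sim_config()].
#' @param keep_masks Keep per-image lesion masks on each bag (used for
#'   saliency evaluation; off by default to save memory).
#' @return List of [image_bag()] objects.
#' @export
generate_dataset <- function(config, keep_masks = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_bags
  n_pos <- round(n * config$class_balance)
  set.seed(config$seed)
  labels <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
  lo <- config$bag_size_range[1]
  hi <- config$bag_size_range[2]
  sizes <- if (lo == hi) rep.int(lo, n) else sample(lo:hi, n, replace = TRUE)
  base_seed <- as.integer(abs(config$seed) %% 1000000007L)
  bags <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(base_seed + i)
    N <- sizes[i]
    if (labels[i] == 1L) {
      n_wit <- max(1L, as.integer(round(config$witness_rate * N)))
      wit <- sample.int(N, n_wit)
      inst <- integer(N)
      inst[wit] <- 1L
    } else {
      inst <- integer(N)
    }
    imgs <- vector("list", N)
    masks <- if (keep_masks) vector("list", N) else NULL
    for (j in seq_len(N)) {
      im <- render_instance(config$image_size, inst[j] == 1L,
                            config$lesion_contrast, config$speckle_sd)
      if (keep_masks) masks[[j]] <- attr(im, "lesion_mask")
      attr(im, "lesion_mask") <- NULL
      imgs[[j]] <- im
    }
    bags[[i]] <- image_bag(sprintf("P%04d", i), imgs, labels[i],
                           instance_labels = inst, lesion_masks = masks)
  }
  bags
}

#' Write a bag dataset to disk as PNGs plus a manifest
#'
#' Saves each image as an 8-bit grayscale PNG under one directory per
#' patient and writes a manifest CSV with columns
#' `patient_id,label,image_path` (one row per image; paths relative to the
#' manifest's directory). All rows of one patient share its bag label.
#'
#' @param bags Non-empty list of [image_bag()] objects.
#' @param out_dir Output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_manifest <- function(bags, out_dir) {
  if (length(bags) == 0L) {
    stop("write_manifest: empty bag list", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("write_manifest: cannot create directory ", out_dir, call. = FALSE)
  }
  rows <- vector("list", length(bags))
  for (b in seq_along(bags)) {
    bag <- bags[[b]]
    pdir <- file.path(out_dir, bag$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    paths <- character(length(bag$images))
    for (j in seq_along(bag$images)) {
      rel <- file.path(bag$patient_id, sprintf("img_%03d.png", j))
      png::writePNG(bag$images[[j]], target = file.path(out_dir, rel))
      paths[j] <- rel
    }
    rows[[b]] <- data.frame(patient_id = bag$patient_id,
                            label = bag$bag_label, image_path = paths,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
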