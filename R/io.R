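# Readers, writers and the evaluation protocol. Conventions fixed
# here: 0-based row-major pixel coordinates with x = column index
# increasing rightward (the axis the CTR extents live on); masks are
# single-channel 8-bit PNGs storing the raw class index per pixel.

#' Write an image / read-write a class mask as PNG
#'
#' Images are written as 8-bit grayscale or RGB; masks as 8-bit single
#' channel PNGs whose pixel values are the class indices themselves,
#' so a mask round-trips bit-identically.
#'
#' @param image `[H, W, C]` array with intensities in `[0, 1]`.
#' @param mask Integer `[H, W]` class mask (values 0-255).
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_image_png <- function(image, path) {
  image <- as_image(image)
  if (dim(image)[3] == 1L) image <- image[, , 1L]
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
write_mask_png <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_mask_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  matrix(as.integer(round(v * 255)), nrow(v), ncol(v))
}

# Bilinear resize for images ([H, W, C]); nearest for masks.
resize_bilinear <- function(img, height, width) {
  d <- dim(img)
  ys <- (seq_len(height) - 0.5) * d[1] / height + 0.5
  xs <- (seq_len(width) - 0.5) * d[2] / width + 0.5
  y0 <- pmin(pmax(floor(ys), 1), d[1]); y1 <- pmin(y0 + 1, d[1])
  x0 <- pmin(pmax(floor(xs), 1), d[2]); x1 <- pmin(x0 + 1, d[2])
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, c(height, width, d[3]))
  wy0 <- matrix(1 - fy, height, width); wy1 <- matrix(fy, height, width)
  wx0 <- matrix(1 - fx, height, width, byrow = TRUE)
  wx1 <- matrix(fx, height, width, byrow = TRUE)
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    out[, , ch] <- m[y0, x0] * wy0 * wx0 + m[y1, x0] * wy1 * wx0 +
      m[y0, x1] * wy0 * wx1 + m[y1, x1] * wy1 * wx1
  }
  out
}

resize_nearest <- function(mask, height, width) {
  d <- dim(mask)
  ys <- pmin(pmax(ceiling((seq_len(height) - 0.5) * d[1] / height), 1), d[1])
  xs <- pmin(pmax(ceiling((seq_len(width) - 0.5) * d[2] / width), 1), d[2])
  mask[ys, xs, drop = FALSE]
}

#' Read an image/mask pair
#'
#' Loads a radiograph and its class mask, validates the mask alphabet
#' for the requested mode, rescales the image to `[0, 1]`, replicates
#' single-channel images to three channels, and resizes both to the
#' working resolution (bilinear for the image, nearest neighbour for
#' the mask).
#'
#' @param image_path,mask_path PNG file paths.
#' @param mode `"multiclass-4"` (labels 0-3) or `"lung-binary-2"`
#'   (labels 0-1).
#' @param size Target `c(height, width)`; `NULL` keeps the stored
#'   resolution. Default 350x350.
#' @return A list with `image` (`[H, W, 3]`) and `mask` (`[H, W]`).
#' @export
read_pair <- function(image_path, mask_path,
                      mode = c("multiclass-4", "lung-binary-2"),
                      size = c(350L, 350L)) {
  mode <- match.arg(mode)
  num_classes <- if (mode == "multiclass-4") 4L else 2L
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(img)[3] == 1L) img <- array(img, c(dim(img)[1:2], 3L))
  mask <- read_mask_png(mask_path)
  bad <- which(mask >= num_classes | mask < 0L)
  if (length(bad)) {
    r <- (bad[1] - 1L) %% nrow(mask) + 1L
    c <- (bad[1] - 1L) %/% nrow(mask) + 1L
    stopf("mask value %d at row %d, column %d of %s is invalid in %s mode",
          mask[bad[1]], r, c, mask_path, mode)
  }
  if (!identical(dim(img)[1:2], dim(mask))) {
    stopf("image (%s) and mask (%s) sizes differ",
          paste(dim(img)[1:2], collapse = "x"),
          paste(dim(mask), collapse = "x"))
  }
  if (!is.null(size)) {
    img <- resize_bilinear(img, size[1], size[2])
    mask <- resize_nearest(mask, size[1], size[2])
  }
  list(image = img, mask = mask)
}

#' Read a dataset directory written by [write_phantom_dataset()]
#'
#' @param dir Directory containing `manifest.tsv` and the PNG pairs.
#' @param mode,size Passed to [read_pair()]; `size = NULL` keeps the
#'   stored resolution.
#' @return A list of `list(image =, mask =, true_ctr =)` samples.
#' @export
read_dataset <- function(dir, mode = "multiclass-4", size = NULL) {
  manifest <- read.delim(file.path(dir, "manifest.tsv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    p <- read_pair(file.path(dir, manifest$image[i]),
                   file.path(dir, manifest$mask[i]), mode = mode,
                   size = size)
    p$true_ctr <- manifest$true_ctr[i]
    p
  })
}

#' Two-fold cross-validation protocol
#'
#' Splits the samples by `fold_id`, trains on fold 1 and evaluates on
#' fold 2, then swaps, and reports the fold-averaged per-class
#' metrics. The training fold can first be expanded with the
#' deterministic augmentation cascade. Passing a `segmenter` function
#' (image -> mask) bypasses training and evaluates that segmenter on
#' both folds, which separates protocol bugs from model quality (a
#' ground-truth oracle must score exactly 1 everywhere).
#'
#' @param samples List of `list(image =, mask =)` samples.
#' @param fold_id Integer vector in `{1, 2}`, one entry per sample.
#' @param spec [make_spec()] describing the network to train.
#' @param config [train_config()].
#' @param augment Expand each training fold with
#'   [build_training_set()]?
#' @param segmenter Optional `function(image) -> mask` evaluated
#'   instead of training.
#' @param mean_over Passed to [score()].
#' @return A list: `average` (fold-averaged `seg_metrics`), `fold1`,
#'   `fold2`, and (when trained) the two `mesh_fit`s.
#' @export
run_protocol <- function(samples, fold_id, spec = make_spec(variant = 2),
                         config = train_config(), augment = FALSE,
                         segmenter = NULL,
                         mean_over = c("foreground", "all")) {
  mean_over <- match.arg(mean_over)
  if (length(fold_id) != length(samples)) {
    stopf("fold_id must assign every sample")
  }
  if (!all(fold_id %in% c(1L, 2L))) stopf("fold ids must be 1 or 2")
  if (!all(c(1L, 2L) %in% fold_id)) stopf("both folds need samples")
  num_classes <- if (is.null(segmenter)) spec$num_classes else {
    max(unlist(lapply(samples, function(s) max(s$mask)))) + 1L
  }

  eval_fold <- function(train_idx, test_idx) {
    fit <- NULL
    seg <- segmenter
    if (is.null(seg)) {
      tr <- samples[train_idx]
      if (augment) tr <- build_training_set(tr)
      fit <- train(assemble(spec, seed = config$seed), tr, config)
      seg <- function(image) segment_image(fit$net, image)
    }
    counts <- NULL
    for (i in test_idx) {
      pred <- seg(samples[[i]]$image)
      cc <- confusion(pred, samples[[i]]$mask, num_classes)
      counts <- if (is.null(counts)) cc else {
        for (col in c("TP", "FP", "FN", "TN")) {
          cc[[col]] <- cc[[col]] + counts[[col]]
        }
        cc
      }
    }
    list(metrics = score(counts, mean_over = mean_over), fit = fit)
  }

  f1 <- eval_fold(which(fold_id == 1L), which(fold_id == 2L))
  f2 <- eval_fold(which(fold_id == 2L), which(fold_id == 1L))
  list(average = twofold_average(f1$metrics, f2$metrics),
       fold1 = f1$metrics, fold2 = f2$metrics,
       fit1 = f1$fit, fit2 = f2$fit)
}

#' Read a plain-text YAML run configuration
#'
#' Reads `phantom`, `network`, and `training` sections into the
#' corresponding config objects; missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return A list with `phantom` ([phantom_config()]), `spec`
#'   ([make_spec()]), and `training` ([train_config()]).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  list(phantom = do.call(phantom_config, as.list(y$phantom)),
       spec = do.call(make_spec, as.list(y$network)),
       training = do.call(train_config, as.list(y$training)))
}
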