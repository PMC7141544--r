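#' Configure a synthetic chest phantom
#'
#' Describes the geometry of a synthetic frontal chest scene: two
#' vertically elongated elliptical lung fields, one elliptical heart
#' shadow overlapping the medial-lower lung area with a weak intensity
#' step at its border, and (optionally) two thin oblique clavicle bars
#' near the apex. The horizontal extent of the heart and of the lung
#' pair are prescribed exactly, so the ground-truth cardiothoracic
#' ratio of a generated sample is `heart_extent / thorax_extent` by
#' construction.
#'
#' Extents are measured as the coordinate difference
#' between the extreme columns of a class (`x_max - x_min`), so
#' `thorax_extent` can be at most `width - 1`.
#'
#' @param height,width Image size in pixels (each at least 32).
#' @param seed Integer seed driving all stochastic content (noise).
#' @param heart_extent Horizontal extent of the heart in pixels.
#' @param thorax_extent Horizontal extent across both lungs in pixels.
#' @param clavicles_present Paint the two clavicle bars (label 3)?
#' @param noise_sd Standard deviation of the additive Gaussian
#'   intensity noise, in intensity units on the `[0, 1]` scale.
#' @param contrast Heart/lung intensity gap in `[0, 1]` before noise.
#' @param center_shift,vertical_shift Whole-scene shifts in pixels,
#'   used by [generate_dataset()] to perturb geometry between samples.
#' @return A `phantom_config` list.
#' @seealso [generate_phantom()], [generate_dataset()]
#' @export
phantom_config <- function(height = 256L, width = 256L, seed = 1L,
                           heart_extent = 90L, thorax_extent = 210L,
                           clavicles_present = TRUE, noise_sd = 0.03,
                           contrast = 0.15, center_shift = 0L,
                           vertical_shift = 0L) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              seed = as.integer(seed),
              heart_extent = as.integer(heart_extent),
              thorax_extent = as.integer(thorax_extent),
              clavicles_present = isTRUE(clavicles_present),
              noise_sd = as.numeric(noise_sd),
              contrast = as.numeric(contrast),
              center_shift = as.integer(center_shift),
              vertical_shift = as.integer(vertical_shift))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (cfg$height < 32L || cfg$width < 32L) {
    stopf("phantom size must be at least 32x32, got %dx%d",
          cfg$height, cfg$width)
  }
  if (cfg$heart_extent <= 0L) {
    stopf("heart_extent must be positive, got %d", cfg$heart_extent)
  }
  if (cfg$heart_extent >= cfg$thorax_extent) {
    stopf("heart_extent (%d) must be smaller than thorax_extent (%d)",
          cfg$heart_extent, cfg$thorax_extent)
  }
  if (cfg$thorax_extent > cfg$width - 1L) {
    stopf(paste0("thorax_extent (%d) cannot exceed width - 1 (%d): ",
                 "extents are coordinate differences between extreme columns"),
          cfg$thorax_extent, cfg$width - 1L)
  }
  if (cfg$noise_sd < 0) stopf("noise_sd must be non-negative")
  if (cfg$contrast < 0 || cfg$contrast > 1) {
    stopf("contrast must lie in [0, 1], got %g", cfg$contrast)
  }
  invisible(cfg)
}

# Rasterize an ellipse on the 0-based pixel grid. `cy` must be an
# integer row so that the extreme columns cx - a and cx + a are hit
# exactly at that row.
ellipse_mask <- function(height, width, cx, cy, a, b) {
  x <- matrix(0:(width - 1L), height, width, byrow = TRUE)
  y <- matrix(0:(height - 1L), height, width)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1 + 1e-9
}

#' Generate one synthetic chest phantom
#'
#' Renders the scene described by a [phantom_config()] into a grayscale
#' image (`[H, W, 1]`, intensities in `[0, 1]`) and an aligned integer
#' class mask (0 = background, 1 = lungs, 2 = heart, 3 = clavicles).
#' The heart takes precedence over the lungs where they overlap, so
#' labels are mutually exclusive. For a fixed config the output is
#' bit-identical across calls.
#'
#' @param config A [phantom_config()].
#' @return A `phantom_sample` list with elements `image`, `mask`,
#'   `true_ctr` (= `heart_extent / thorax_extent`), and `config`.
#' @examples
#' s <- generate_phantom(phantom_config(seed = 7))
#' s$true_ctr
#' @export
generate_phantom <- function(config) {
  validate_phantom_config(config)
  H <- config$height; W <- config$width
  te <- config$thorax_extent; he <- config$heart_extent

  tx0 <- as.integer(round((W - 1L - te) / 2)) + config$center_shift
  tx1 <- tx0 + te
  if (tx0 < 0L || tx1 > W - 1L) {
    stopf("thorax span [%d, %d] leaves the %d-pixel-wide image", tx0, tx1, W)
  }

  a_l <- 0.23 * te
  cy_l <- round(0.52 * (H - 1) + config$vertical_shift)
  b_l <- 0.32 * (H - 1)
  lungs <- ellipse_mask(H, W, tx0 + a_l, cy_l, a_l, b_l) |
    ellipse_mask(H, W, tx1 - a_l, cy_l, a_l, b_l)

  hx0 <- as.integer(round((tx0 + tx1) / 2 - 0.02 * W - he / 2))
  hx0 <- min(max(hx0, tx0 + 2L), tx1 - 2L - he)
  hx1 <- hx0 + he
  cy_h <- round(0.70 * (H - 1) + config$vertical_shift)
  b_h <- 0.16 * (H - 1)
  heart <- ellipse_mask(H, W, hx0 + he / 2, cy_h, he / 2, b_h)

  mask <- matrix(0L, H, W)
  mask[lungs] <- 1L

  if (config$clavicles_present) {
    y0 <- 0.18 * (H - 1) + config$vertical_shift
    half_len <- 0.16 * W
    thick <- max(1, 0.008 * H)
    xg <- matrix(0:(W - 1L), H, W, byrow = TRUE)
    yg <- matrix(0:(H - 1L), H, W)
    for (side in c(-1, 1)) {
      cx_s <- if (side < 0) tx0 + a_l else tx1 - a_l
      clav <- abs(xg - cx_s) <= half_len &
        abs(yg - (y0 + side * 0.15 * (xg - cx_s))) <= thick &
        xg >= tx0 + 1L & xg <= tx1 - 1L
      mask[clav] <- 3L
    }
  }

  mask[heart] <- 2L

  # By-construction guarantees the downstream CTR math relies on.
  lung_cols <- range(which(apply(mask == 1L, 2, any))) - 1L
  heart_cols <- range(which(apply(mask == 2L, 2, any))) - 1L
  stopifnot(identical(lung_cols, c(tx0, tx1)),
            identical(heart_cols, c(hx0, hx1)))

  levels <- c(0.55, 0.30, 0.30 + config$contrast, 0.85)
  img <- matrix(levels[mask + 1L], H, W)
  img <- with_seed(config$seed, img + rnorm(H * W, sd = config$noise_sd))
  img <- pmin(pmax(img, 0), 1)

  structure(list(image = array(img, c(H, W, 1L)),
                 mask = mask,
                 true_ctr = he / te,
                 config = config),
            class = "phantom_sample")
}

#' Generate a reproducible phantom dataset
#'
#' Draws `n` phantoms whose geometry (thorax width, heart width and
#' hence ground-truth CTR, scene shifts) and noise realization are
#' independently perturbed around the base `config`. CTRs are drawn
#' uniformly from `[0.36, 0.56]`, straddling the conventional 0.5
#' cardiomegaly threshold.
#'
#' @param config Base [phantom_config()].
#' @param n Number of samples (`n = 0` gives an empty list).
#' @param seed Integer seed; the same seed reproduces the identical
#'   sample sequence.
#' @return A list of `phantom_sample` objects.
#' @export
generate_dataset <- function(config, n, seed = config$seed) {
  validate_phantom_config(config)
  if (n < 0) stopf("n must be non-negative")
  if (n == 0) return(list())
  draws <- with_seed(seed, data.frame(
    te_scale = runif(n, 0.88, 1.0),
    ctr = runif(n, 0.36, 0.56),
    cs = round(runif(n, -0.03, 0.03) * config$width),
    vs = round(runif(n, -0.03, 0.03) * config$height),
    seed = sample.int(.Machine$integer.max - 1L, n)))
  lapply(seq_len(n), function(i) {
    te <- round(config$thorax_extent * draws$te_scale[i])
    he <- max(2L, round(draws$ctr[i] * te))
    cfg <- config
    cfg$thorax_extent <- as.integer(te)
    cfg$heart_extent <- as.integer(he)
    cfg$center_shift <- as.integer(draws$cs[i])
    cfg$vertical_shift <- as.integer(draws$vs[i])
    cfg$seed <- draws$seed[i]
    generate_phantom(cfg)
  })
}

#' Write a phantom dataset as paired PNG files
#'
#' Writes `image_NNNN.png` (8-bit grayscale) and `mask_NNNN.png` (8-bit
#' single channel holding the raw class indices 0-3) for every sample,
#' plus a tab-separated `manifest.tsv` listing the file pairs and each
#' sample's ground-truth CTR.
#'
#' @param samples List of `phantom_sample` objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_phantom_dataset <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    img_file <- sprintf("image_%04d.png", i)
    mask_file <- sprintf("mask_%04d.png", i)
    write_image_png(s$image, file.path(dir, img_file))
    write_mask_png(s$mask, file.path(dir, mask_file))
    data.frame(image = img_file, mask = mask_file,
               true_ctr = if (is.null(s$true_ctr)) NA_real_ else s$true_ctr)
  })
  manifest <- do.call(rbind, rows)
  write.table2(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

write.table2 <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
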