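#' Describe one augmentation step
#'
#' A step translates an image/mask pair by `(dx, dy)` pixels (positive
#' `dx` moves content rightward, positive `dy` downward) and then
#' optionally flips it horizontally. Images are resampled bilinearly,
#' masks by nearest neighbour so no fractional class labels can appear.
#'
#' @param dx,dy Signed translation in pixels.
#' @param hflip Apply a horizontal flip after translating?
#' @return An `augment_step` list.
#' @export
augment_step <- function(dx = 0, dy = 0, hflip = FALSE) {
  structure(list(dx = dx, dy = dy, hflip = isTRUE(hflip)),
            class = "augment_step")
}

# Bilinear translation with zero fill; works for fractional shifts.
translate_bilinear <- function(img, dx, dy) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  ys <- seq_len(H) - dy          # source row for each output row
  xs <- seq_len(W) - dx
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  out <- array(0, d)
  at <- function(r, c) {
    ok_r <- r >= 1 & r <= H
    ok_c <- c >= 1 & c <= W
    v <- array(0, d)
    if (any(ok_r) && any(ok_c)) {
      v[ok_r, ok_c, ] <- img[r[ok_r], c[ok_c], , drop = FALSE]
    }
    v
  }
  wy0 <- matrix(1 - fy, H, W); wy1 <- matrix(fy, H, W)
  wx0 <- matrix(1 - fx, H, W, byrow = TRUE); wx1 <- matrix(fx, H, W, byrow = TRUE)
  a00 <- at(y0, x0); a10 <- at(y0 + 1, x0)
  a01 <- at(y0, x0 + 1); a11 <- at(y0 + 1, x0 + 1)
  for (ch in seq_len(d[3])) {
    out[, , ch] <- a00[, , ch] * wy0 * wx0 + a10[, , ch] * wy1 * wx0 +
      a01[, , ch] * wy0 * wx1 + a11[, , ch] * wy1 * wx1
  }
  out
}

translate_nearest <- function(mask, dx, dy) {
  d <- dim(mask)
  H <- d[1]; W <- d[2]
  ys <- round(seq_len(H) - dy)
  xs <- round(seq_len(W) - dx)
  out <- matrix(0L, H, W)
  ok_r <- ys >= 1 & ys <= H
  ok_c <- xs >= 1 & xs <= W
  out[ok_r, ok_c] <- mask[ys[ok_r], xs[ok_c]]
  out
}

#' Apply one augmentation step to an image/mask pair
#'
#' @param image `[H, W, C]` numeric array.
#' @param mask `[H, W]` integer class mask aligned to `image`.
#' @param step An [augment_step()].
#' @return A list with the transformed `image` and `mask`, same
#'   dimensions as the input; vacated borders are filled with 0
#'   (intensity) and the background label 0.
#' @export
apply_step <- function(image, mask, step) {
  image <- as_image(image)
  mask <- as_mask(mask)
  check_pair_dims(image, mask)
  img <- translate_bilinear(image, step$dx, step$dy)
  msk <- translate_nearest(mask, step$dx, step$dy)
  if (step$hflip) {
    W <- dim(img)[2]
    img <- img[, W:1, , drop = FALSE]
    msk <- msk[, W:1, drop = FALSE]
  }
  list(image = img, mask = msk)
}

#' Expand training pairs with the deterministic translation/flip cascade
#'
#' Five-stage cascade, each stage appending a transformed copy of the
#' running set: (1) translate (+5, -5) without flip; (2) horizontal
#' flip; (3) translate (-5, +5) with flip; (4) two parallel branches,
#' translate (+10, +10) with flip and translate (-10, -10) with flip,
#' each branch again appending to the stage-3 set; the final set is the
#' concatenation of both branches (the stage-3 pairs therefore appear
#' twice). Cardinalities for `n` input pairs run
#' `n -> 2n -> 4n -> 8n -> 32n`, so 124 pairs expand to 992 after stage
#' 3 and to 3968 (1984 + 1984) overall.
#'
#' @param pairs Non-empty list of `list(image =, mask =)` pairs (e.g.
#'   `phantom_sample` objects).
#' @return An `augmented_set`: list with `pairs` (the expanded list)
#'   and `provenance` (per-pair character label of the applied step
#'   chain).
#' @export
build_training_set <- function(pairs) {
  if (length(pairs) == 0) stopf("input pair list is empty")
  pairs <- lapply(pairs, function(p) list(image = as_image(p$image),
                                          mask = as_mask(p$mask)))
  prov <- rep("orig", length(pairs))

  grow <- function(set, prov, step, label) {
    extra <- lapply(set, function(p) apply_step(p$image, p$mask, step))
    list(pairs = c(set, extra), prov = c(prov, paste(prov, label, sep = "|")))
  }

  s1 <- grow(pairs, prov, augment_step(5, -5, FALSE), "t(+5,-5)")
  s2 <- grow(s1$pairs, s1$prov, augment_step(0, 0, TRUE), "hflip")
  s3 <- grow(s2$pairs, s2$prov, augment_step(-5, 5, TRUE), "t(-5,+5)+hflip")
  bA <- grow(s3$pairs, s3$prov, augment_step(10, 10, TRUE), "t(+10,+10)+hflip")
  bB <- grow(s3$pairs, s3$prov, augment_step(-10, -10, TRUE), "t(-10,-10)+hflip")

  structure(list(pairs = c(bA$pairs, bB$pairs),
                 provenance = c(bA$prov, bB$prov),
                 stage_sizes = c(input = length(pairs),
                                 stage1 = length(s1$pairs),
                                 stage2 = length(s2$pairs),
                                 stage3 = length(s3$pairs),
                                 final = 2L * length(bA$pairs))),
            class = "augmented_set")
}

#' @export
length.augmented_set <- function(x) length(x$pairs)

#' @export
print.augmented_set <- function(x, ...) {
  cat(sprintf("augmented_set: %d pairs (stages %s)\n", length(x$pairs),
              paste(x$stage_sizes, collapse = " -> ")))
  invisible(x)
}
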