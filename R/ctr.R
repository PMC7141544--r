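#' Cardiothoracic ratio from horizontal extents
#'
#' `CTR = AB / CD`, where `AB` is the horizontal extent of the heart
#' (distance between its extreme left and right points) and `CD` the
#' extent across both lungs, both in pixels on the same frontal image.
#'
#' @param AB Heart extent in pixels (non-negative).
#' @param CD Thoracic extent in pixels (positive).
#' @return The ratio `AB / CD`.
#' @examples
#' ctr_from_extents(130, 302)   # 0.4305
#' @export
ctr_from_extents <- function(AB, CD) {
  if (CD <= 0) stopf("thoracic extent CD must be positive, got %g", CD)
  if (AB < 0) stopf("heart extent AB must be non-negative, got %g", AB)
  AB / CD
}

#' Compute the cardiothoracic ratio from a class mask
#'
#' Extracts the heart and lung extreme columns from a multiclass
#' segmentation mask and forms the CTR as the ratio of coordinate
#' differences `AB = x_max(heart) - x_min(heart)` over
#' `CD = x_max(lungs) - x_min(lungs)` (both lungs pooled). A mask with
#' no heart or no lung pixels has no defined CTR and raises an error
#' rather than returning 0.
#'
#' @param mask Integer `[H, W]` mask; columns are the horizontal axis.
#' @param threshold Cardiomegaly decision threshold on the CTR
#'   (default 0.5; clinical thresholds vary with age group).
#' @param lung_label,heart_label Class indices for lungs and heart.
#' @param largest_component Restrict each class to its largest
#'   4-connected component before taking extremes (useful for noisy
#'   predicted masks; off by default).
#' @return A `ctr_result` list: `AB`, `CD`, `ctr`, `cardiomegaly`
#'   (`ctr > threshold`), `threshold`.
#' @examples
#' s <- generate_phantom(phantom_config(heart_extent = 100,
#'                                      thorax_extent = 250,
#'                                      width = 256))
#' compute_ctr(s$mask)$ctr   # 0.4 by construction
#' @export
compute_ctr <- function(mask, threshold = 0.5, lung_label = 1L,
                        heart_label = 2L, largest_component = FALSE) {
  mask <- as_mask(mask)
  heart <- mask == heart_label
  lungs <- mask == lung_label
  if (!any(heart)) stopf("undefined CTR: mask contains no heart pixels")
  if (!any(lungs)) stopf("undefined CTR: mask contains no lung pixels")
  if (largest_component) {
    heart <- largest_cc(heart)
    lungs <- largest_cc(lungs, keep = 2L)
  }
  xr_h <- range(which(apply(heart, 2, any)))
  xr_l <- range(which(apply(lungs, 2, any)))
  AB <- diff(xr_h)
  CD <- diff(xr_l)
  structure(list(AB = AB, CD = CD, ctr = ctr_from_extents(AB, CD),
                 cardiomegaly = ctr_from_extents(AB, CD) > threshold,
                 threshold = threshold),
            class = "ctr_result")
}

#' @export
print.ctr_result <- function(x, ...) {
  cat(sprintf("AB = %d px, CD = %d px, CTR = %.4f (threshold %.2f) -> %s\n",
              x$AB, x$CD, x$ctr, x$threshold,
              if (x$cardiomegaly) "cardiomegaly" else "normal"))
  invisible(x)
}

# Keep the `keep` largest 4-connected components of a logical matrix
# (two for the lung fields, one for the heart).
largest_cc <- function(bin, keep = 1L) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  cur <- 0L
  idx_all <- which(bin)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- (p - 1L) %% H + 1L
      cc <- (p - 1L) %/% H + 1L
      for (q in c(if (r > 1) p - 1L, if (r < H) p + 1L,
                  if (cc > 1) p - H, if (cc < W) p + H)) {
        if (bin[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  if (cur <= keep) return(bin)
  sizes <- tabulate(lab[lab > 0L], nbins = cur)
  top <- order(sizes, decreasing = TRUE)[seq_len(keep)]
  matrix(lab %in% top, H, W)
}
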