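# Internal helpers shared across modules.

# Run `expr` under a private RNG state seeded with `seed`, restoring the
# caller's state afterwards, so generators are deterministic without
# clobbering the session RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Coerce an image to the canonical [H, W, C] numeric array in [0, 1].
as_image <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    stopf("image must be a [H, W, C] array or an [H, W] matrix")
  }
  storage.mode(x) <- "double"
  x
}

# Coerce a label mask to an integer [H, W] matrix.
as_mask <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 1L) {
    x <- x[, , 1L]
  }
  if (!is.matrix(x)) stopf("mask must be an [H, W] matrix")
  storage.mode(x) <- "integer"
  x
}

check_pair_dims <- function(image, mask) {
  if (!identical(dim(image)[1:2], dim(mask))) {
    stopf("image (%s) and mask (%s) spatial dimensions differ",
          paste(dim(image)[1:2], collapse = "x"),
          paste(dim(mask), collapse = "x"))
  }
  invisible(TRUE)
}
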