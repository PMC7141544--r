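# Differentiable layer wrappers around the compiled primitives.
# Tensors are [H, W, C, N] double arrays throughout; the batch axis is
# last so per-channel statistics reduce over (H, W, N).

conv_fwd <- function(x, W, b, k, pad) {
  cpp_conv_forward(x, W, b, k, k, pad)
}

conv_bwd <- function(x, W, gy, k, pad) {
  cpp_conv_backward(x, W, gy, k, k, pad)
}

# Fused batch normalization + ReLU ("~" stage). In training mode the
# batch statistics normalize and the running statistics are updated
# with momentum 0.1; in inference mode the running statistics are used.
bnrelu_fwd <- function(x, gamma, beta, run, train, eps = 1e-5,
                       momentum = 0.1) {
  d <- dim(x)
  M <- d[1] * d[2] * d[4]
  if (train) {
    st <- cpp_channel_stats(x)
    mu <- st$sum / M
    var <- st$sumsq / M - mu^2
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * var
  } else {
    mu <- run$mean
    var <- run$var
  }
  invstd <- 1 / sqrt(var + eps)
  fw <- cpp_bnrelu_forward(x, mu, invstd, gamma, beta)
  list(y = fw$y, run = run, cache = list(xhat = fw$xhat, invstd = invstd))
}

bnrelu_bwd <- function(dy, y, cache, gamma) {
  cpp_bnrelu_backward(dy, y, cache$xhat, gamma, cache$invstd)
}

# Per-pixel softmax over the class axis of [H, W, K, N] scores.
softmax4 <- function(z) {
  d <- dim(z)
  HW <- d[1] * d[2]; K <- d[3]; N <- d[4]
  dim(z) <- c(HW, K, N)
  mx <- z[, 1, , drop = FALSE]
  for (k in seq_len(K)[-1]) mx <- pmax(mx, z[, k, , drop = FALSE])
  for (k in seq_len(K)) z[, k, ] <- exp(z[, k, , drop = FALSE] - mx)
  ssum <- z[, 1, , drop = FALSE]
  for (k in seq_len(K)[-1]) ssum <- ssum + z[, k, , drop = FALSE]
  for (k in seq_len(K)) z[, k, ] <- z[, k, , drop = FALSE] / ssum
  dim(z) <- d
  z
}

# Linear indices of the target-class entry of every pixel in a
# [H, W, K, N] probability tensor, given 0-based targets [H, W, N].
target_lin_idx <- function(target, HW, K, N) {
  hw <- rep.int(0:(HW - 1L), N)
  n_off <- rep(0:(N - 1L), each = HW) * (HW * K)
  hw + HW * as.vector(target) + n_off + 1L
}

#' Median-frequency-balanced weighted cross-entropy loss
#'
#' `loss = -(1/N) * sum_pixels w[y] * log p[y]` over all `N` pixels of
#' the batch, with per-class weights `w` (e.g. from
#' [median_frequency_weights()]). Zero exactly when every pixel assigns
#' probability 1 to its target class.
#'
#' @param scores `[H, W, K, N]` per-pixel class probabilities (each
#'   pixel's scores sum to 1), or `[H, W, K]` for a single image.
#' @param target Integer `[H, W, N]` (or `[H, W]`) mask of 0-based
#'   class labels.
#' @param weights Per-class weight vector of length `K`.
#' @return The scalar loss.
#' @export
weighted_cross_entropy <- function(scores, target, weights) {
  if (length(dim(scores)) == 3L) dim(scores) <- c(dim(scores), 1L)
  if (is.matrix(target)) dim(target) <- c(dim(target), 1L)
  d <- dim(scores)
  if (!identical(dim(target), d[c(1, 2, 4)])) {
    stopf("scores (%s) and target (%s) shapes are incompatible",
          paste(d, collapse = "x"), paste(dim(target), collapse = "x"))
  }
  HW <- d[1] * d[2]; K <- d[3]; N <- d[4]
  if (length(weights) != K) stopf("need %d class weights, got %d",
                                  K, length(weights))
  lin <- target_lin_idx(target, HW, K, N)
  wy <- weights[as.vector(target) + 1L]
  -sum(wy * log(pmax(scores[lin], 1e-300))) / (HW * N)
}

# Loss gradient with respect to the pre-softmax logits:
# d loss / d z_k = (w_y / N) * (p_k - 1{k == y}).
wce_logit_grad <- function(probs, target, weights) {
  d <- dim(probs)
  HW <- d[1] * d[2]; K <- d[3]; N <- d[4]
  wy <- weights[as.vector(target) + 1L] / (HW * N)
  g <- probs
  dim(g) <- c(HW, K, N)
  wym <- matrix(wy, HW, N)
  for (k in seq_len(K)) g[, k, ] <- g[, k, , drop = FALSE] *
      array(wym, c(HW, 1L, N))
  dim(g) <- d
  lin <- target_lin_idx(target, HW, K, N)
  g[lin] <- g[lin] - wy
  g
}

pixel_accuracy <- function(probs, target) {
  d <- dim(probs)
  HW <- d[1] * d[2]; K <- d[3]; N <- d[4]
  dim(probs) <- c(HW, K, N)
  best <- matrix(0L, HW, N)
  bv <- matrix(-Inf, HW, N)
  for (k in seq_len(K)) {
    pk <- matrix(probs[, k, ], HW, N)
    upd <- pk > bv
    best[upd] <- k - 1L
    bv[upd] <- pk[upd]
  }
  mean(best == as.vector(target))
}
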