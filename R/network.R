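#' Declare a residual-mesh encoder-decoder network
#'
#' The architecture is a four-block encoder / four-block decoder fully
#' convolutional network. Each encoder block holds two 3x3
#' convolutions joined by an inner identity stream (elementwise
#' addition of the first conv's raw output to the second's), a batch
#' norm + ReLU after the first conv and after the addition, and a 2x2
#' max-pooling that records its argmax indices. Each decoder block
#' starts with a max-unpooling driven by the paired encoder block's
#' indices, mirrors the two convolutions, and sums three terms: the
#' second conv output, a projection of the first conv output (a 1x1
#' convolution in blocks 1-3, identity in block 4), and an encoder
#' feature carried over an outer identity stream. A final 3x3 mask
#' convolution and per-pixel softmax produce the class scores. The 12
#' residual additions (4 encoder inner, 4 outer, 3 non-identity
#' decoder inner, 1 identity decoder inner) form the residual mesh.
#'
#' Variant 1 uses the full filter chain 64-128-256-512; variant 2
#' halves every width, cutting the trainable parameters by about 75%.
#' Arbitrary positive `width_multiplier`s are allowed for small-scale
#' experiments.
#'
#' @param variant 1 (multiplier 1.0) or 2 (multiplier 0.5); ignored if
#'   `width_multiplier` is given.
#' @param width_multiplier Scale applied to the base widths
#'   `c(64, 128, 256, 512)`; widths round to the nearest integer, at
#'   least 1.
#' @param num_classes Output classes (4 for background/lungs/heart/
#'   clavicles, 2 for lung-only masks).
#' @param input_channels Image channels expected by the first
#'   convolution (3 by default; grayscale input is replicated by the
#'   readers).
#' @return A `mesh_spec` list with `encoder_widths` and per-block
#'   `decoder_widths` (first-conv, second-conv pairs).
#' @examples
#' make_spec(variant = 1)$encoder_widths    # 64 128 256 512
#' make_spec(variant = 2)$encoder_widths    # 32  64 128 256
#' @export
make_spec <- function(variant = NULL, width_multiplier = NULL,
                      num_classes = 4L, input_channels = 3L) {
  if (is.null(width_multiplier)) {
    if (is.null(variant)) variant <- 1L
    if (!variant %in% c(1L, 2L)) stopf("variant must be 1 or 2")
    width_multiplier <- c(1, 0.5)[variant]
  }
  if (width_multiplier <= 0) stopf("width_multiplier must be positive")
  if (num_classes < 2) stopf("num_classes must be at least 2")
  if (input_channels < 1) stopf("input_channels must be at least 1")
  ew <- pmax(1L, as.integer(round(c(64, 128, 256, 512) * width_multiplier)))
  dw <- lapply(1:4, function(j) {
    c(first = ew[5L - j], second = ew[max(4L - j, 1L)])
  })
  structure(list(width_multiplier = width_multiplier,
                 num_classes = as.integer(num_classes),
                 input_channels = as.integer(input_channels),
                 encoder_widths = ew,
                 decoder_widths = dw),
            class = "mesh_spec")
}

bn_names <- function() {
  c(sprintf("enc%d_bna", 1:4), sprintf("enc%d_bns", 1:4),
    sprintf("dec%d_bna", 1:4), sprintf("dec%d_bns", 1:4))
}

# He-normal initialization for a conv weight matrix Cout x (k*k*Cin).
init_conv <- function(cout, cin, k) {
  fan_in <- k * k * cin
  matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in)
}

#' Assemble an executable network from a spec
#'
#' Instantiates all trainable tensors (He-normal conv kernels, zero
#' biases, unit/zero batch-norm scale/shift) and the layer/residual
#' bookkeeping. Channel compatibility of every residual addition is
#' checked here, so a malformed spec fails at assembly rather than
#' during a forward pass.
#'
#' @param spec A [make_spec()] result.
#' @param seed Integer seed for the weight initialization.
#' @return A `mesh_net` list: `spec`, `params` (named list of
#'   trainable tensors), `running` (batch-norm running statistics),
#'   `layers` (layer census data frame), `paths` (residual path
#'   census data frame).
#' @export
assemble <- function(spec, seed = 1L) {
  if (!inherits(spec, "mesh_spec")) stopf("spec must come from make_spec()")
  ew <- spec$encoder_widths
  if (length(ew) != 4L || any(ew < 1L)) {
    stopf("encoder must have 4 positive widths")
  }
  for (j in 1:4) {
    dwj <- spec$decoder_widths[[j]]
    want <- c(ew[5L - j], ew[max(4L - j, 1L)])
    if (!identical(as.integer(dwj), as.integer(want))) {
      stopf(paste0("decoder block %d widths (%s) break residual-path ",
                   "channel compatibility (need %s)"),
            j, paste(dwj, collapse = ","), paste(want, collapse = ","))
    }
  }

  params <- list()
  layers <- list()
  add_layer <- function(name, kind, kernel, cin, cout, n) {
    layers[[length(layers) + 1L]] <<- data.frame(
      name = name, kind = kind, kernel = kernel,
      in_ch = cin, out_ch = cout, n_params = n)
  }

  with_seed(seed, {
    cin <- spec$input_channels
    for (i in 1:4) {
      w <- ew[i]
      params[[sprintf("enc%d_a_W", i)]] <- init_conv(w, cin, 3L)
      params[[sprintf("enc%d_a_b", i)]] <- numeric(w)
      add_layer(sprintf("enc%d_conv_a", i), "conv3", 3L, cin, w, 9 * cin * w + w)
      params[[sprintf("enc%d_bna_gamma", i)]] <- rep(1, w)
      params[[sprintf("enc%d_bna_beta", i)]] <- numeric(w)
      add_layer(sprintf("enc%d_bna", i), "bn", 0L, w, w, 2 * w)
      params[[sprintf("enc%d_b_W", i)]] <- init_conv(w, w, 3L)
      params[[sprintf("enc%d_b_b", i)]] <- numeric(w)
      add_layer(sprintf("enc%d_conv_b", i), "conv3", 3L, w, w, 9 * w * w + w)
      params[[sprintf("enc%d_bns_gamma", i)]] <- rep(1, w)
      params[[sprintf("enc%d_bns_beta", i)]] <- numeric(w)
      add_layer(sprintf("enc%d_bns", i), "bn", 0L, w, w, 2 * w)
      add_layer(sprintf("enc%d_pool", i), "maxpool", 2L, w, w, 0)
      cin <- w
    }
    for (j in 1:4) {
      dwj <- spec$decoder_widths[[j]]
      w1 <- dwj[[1]]; w2 <- dwj[[2]]
      add_layer(sprintf("dec%d_unpool", j), "unpool", 2L, w1, w1, 0)
      params[[sprintf("dec%d_a_W", j)]] <- init_conv(w1, w1, 3L)
      params[[sprintf("dec%d_a_b", j)]] <- numeric(w1)
      add_layer(sprintf("dec%d_conv_a", j), "conv3", 3L, w1, w1, 9 * w1 * w1 + w1)
      params[[sprintf("dec%d_bna_gamma", j)]] <- rep(1, w1)
      params[[sprintf("dec%d_bna_beta", j)]] <- numeric(w1)
      add_layer(sprintf("dec%d_bna", j), "bn", 0L, w1, w1, 2 * w1)
      params[[sprintf("dec%d_b_W", j)]] <- init_conv(w2, w1, 3L)
      params[[sprintf("dec%d_b_b", j)]] <- numeric(w2)
      add_layer(sprintf("dec%d_conv_b", j), "conv3", 3L, w1, w2, 9 * w1 * w2 + w2)
      if (j <= 3) {
        # non-identity projection, 1x1 and bias-free
        params[[sprintf("dec%d_f_W", j)]] <- init_conv(w2, w1, 1L)
        add_layer(sprintf("dec%d_proj", j), "conv1", 1L, w1, w2, w1 * w2)
      }
      params[[sprintf("dec%d_bns_gamma", j)]] <- rep(1, w2)
      params[[sprintf("dec%d_bns_beta", j)]] <- numeric(w2)
      add_layer(sprintf("dec%d_bns", j), "bn", 0L, w2, w2, 2 * w2)
    }
    k <- spec$num_classes
    params[["mconv_W"]] <- init_conv(k, ew[1], 3L)
    params[["mconv_b"]] <- numeric(k)
    add_layer("mconv", "conv3", 3L, ew[1], k, 9 * ew[1] * k + k)
  })

  running <- setNames(lapply(bn_names(), function(nm) {
    w <- length(params[[paste0(nm, "_gamma")]])
    list(mean = numeric(w), var = rep(1, w))
  }), bn_names())

  paths <- rbind(
    data.frame(stream = "IIS", mapping = "identity",
               source = sprintf("enc%d_conv_a", 1:4),
               destination = sprintf("enc%d_sum", 1:4)),
    data.frame(stream = "OIS", mapping = "identity",
               source = c("enc3_pool", "enc2_pool", "enc1_pool",
                          "enc1_conv_a"),
               destination = sprintf("dec%d_sum", 1:4)),
    data.frame(stream = "INIS", mapping = "nonidentity",
               source = sprintf("dec%d_conv_a", 1:3),
               destination = sprintf("dec%d_sum", 1:3)),
    data.frame(stream = "IIS", mapping = "identity",
               source = "dec4_conv_a", destination = "dec4_sum"))

  structure(list(spec = spec, params = params, running = running,
                 layers = do.call(rbind, layers), paths = paths),
            class = "mesh_net")
}

#' @export
print.mesh_net <- function(x, ...) {
  cat(sprintf(paste0("residual-mesh network: width multiplier %g, ",
                     "%d classes, %d input channels\n"),
              x$spec$width_multiplier, x$spec$num_classes,
              x$spec$input_channels))
  cat(sprintf("  encoder widths: %s\n",
              paste(x$spec$encoder_widths, collapse = " ")))
  cat(sprintf("  %d trainable parameters; %d 3x3 conv layers; %d residual paths\n",
              count_parameters(x), sum(x$layers$kind == "conv3"),
              nrow(x$paths)))
  invisible(x)
}

#' Count trainable parameters
#'
#' Sums the sizes of every trainable tensor: convolution kernels and
#' biases plus batch-norm scale/shift. Running statistics are not
#' trainable and are excluded.
#'
#' @param net A [assemble()]d network.
#' @return Integer parameter count.
#' @export
count_parameters <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

#' Enumerate the residual mesh
#'
#' @param net A [assemble()]d network.
#' @return A `residual_census` list: `total`, `identity`,
#'   `nonidentity`, and the per-path data frame `paths` (stream kind,
#'   source layer, destination, mapping).
#' @export
census_residual_paths <- function(net) {
  p <- net$paths
  structure(list(total = nrow(p),
                 identity = sum(p$mapping == "identity"),
                 nonidentity = sum(p$mapping == "nonidentity"),
                 paths = p),
            class = "residual_census")
}

#' @export
print.residual_census <- function(x, ...) {
  cat(sprintf("%d residual paths: %d identity, %d nonidentity\n",
              x$total, x$identity, x$nonidentity))
  print(x$paths, row.names = FALSE)
  invisible(x)
}

# Full forward pass. `x` is [H, W, C, N] (or [H, W, C]); returns the
# per-pixel class probabilities plus (optionally) the cache needed by
# the backward pass and the per-stage feature-map shapes.
forward_mesh <- function(net, x, train = FALSE, keep_cache = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] < 16L || d[2] < 16L) {
    stopf("input %dx%d is too small: both sides must be at least 16",
          d[1], d[2])
  }
  if (d[3] != net$spec$input_channels) {
    stopf("input has %d channels but the network expects %d",
          d[3], net$spec$input_channels)
  }
  p <- net$params
  run <- net$running
  enc_cache <- vector("list", 4L)
  ois <- vector("list", 4L)
  shapes <- list(input = d[1:2])
  cur <- x

  for (i in 1:4) {
    Tt <- conv_fwd(cur, p[[sprintf("enc%d_a_W", i)]],
                   p[[sprintf("enc%d_a_b", i)]], 3L, 1L)
    nma <- sprintf("enc%d_bna", i)
    fa <- bnrelu_fwd(Tt, p[[paste0(nma, "_gamma")]], p[[paste0(nma, "_beta")]],
                     run[[nma]], train)
    run[[nma]] <- fa$run
    Ta <- fa$y
    K <- conv_fwd(Ta, p[[sprintf("enc%d_b_W", i)]],
                  p[[sprintf("enc%d_b_b", i)]], 3L, 1L)
    R <- Tt + K
    nms <- sprintf("enc%d_bns", i)
    fs <- bnrelu_fwd(R, p[[paste0(nms, "_gamma")]], p[[paste0(nms, "_beta")]],
                     run[[nms]], train)
    run[[nms]] <- fs$run
    Ra <- fs$y
    pl <- cpp_maxpool(Ra)
    if (i == 1L) ois[[4L]] <- Ta
    if (i <= 3L) ois[[4L - i]] <- pl$y
    enc_cache[[i]] <- list(x_in = if (keep_cache) cur else NULL,
                           Ta = if (keep_cache) Ta else NULL,
                           bna = if (keep_cache) fa$cache else NULL,
                           Ra = if (keep_cache) Ra else NULL,
                           bns = if (keep_cache) fs$cache else NULL,
                           idx = pl$idx, pre_dim = dim(Ra))
    shapes[[sprintf("enc%d", i)]] <- dim(pl$y)[1:2]
    cur <- pl$y
  }
  shapes$deepest <- dim(cur)[1:2]

  dec_cache <- vector("list", 4L)
  for (j in 1:4) {
    i <- 5L - j
    pd <- enc_cache[[i]]$pre_dim
    up <- cpp_pool_scatter(cur, enc_cache[[i]]$idx, pd[1], pd[2])
    Tt <- conv_fwd(up, p[[sprintf("dec%d_a_W", j)]],
                   p[[sprintf("dec%d_a_b", j)]], 3L, 1L)
    nma <- sprintf("dec%d_bna", j)
    fa <- bnrelu_fwd(Tt, p[[paste0(nma, "_gamma")]], p[[paste0(nma, "_beta")]],
                     run[[nma]], train)
    run[[nma]] <- fa$run
    Ta <- fa$y
    K <- conv_fwd(Ta, p[[sprintf("dec%d_b_W", j)]],
                  p[[sprintf("dec%d_b_b", j)]], 3L, 1L)
    P <- if (j <= 3L) {
      Wf <- p[[sprintf("dec%d_f_W", j)]]
      conv_fwd(Tt, Wf, numeric(nrow(Wf)), 1L, 0L)
    } else Tt
    S <- ois[[j]] + K + P
    nms <- sprintf("dec%d_bns", j)
    fs <- bnrelu_fwd(S, p[[paste0(nms, "_gamma")]], p[[paste0(nms, "_beta")]],
                     run[[nms]], train)
    run[[nms]] <- fs$run
    Sa <- fs$y
    dec_cache[[j]] <- list(up = if (keep_cache) up else NULL,
                           Tt = if (keep_cache) Tt else NULL,
                           Ta = if (keep_cache) Ta else NULL,
                           bna = if (keep_cache) fa$cache else NULL,
                           Sa = if (keep_cache) Sa else NULL,
                           bns = if (keep_cache) fs$cache else NULL)
    shapes[[sprintf("dec%d", j)]] <- dim(Sa)[1:2]
    cur <- Sa
  }

  logits <- conv_fwd(cur, p$mconv_W, p$mconv_b, 3L, 1L)
  probs <- softmax4(logits)
  out <- list(probs = probs, shapes = shapes, running = run)
  if (keep_cache) {
    out$cache <- list(enc = enc_cache, dec = dec_cache)
  }
  out
}

# Backward pass from the loss gradient at the logits. Returns a named
# list of gradients matching net$params.
backward_mesh <- function(net, cache, dlogits) {
  p <- net$params
  g <- list()
  cb <- conv_bwd(cache$dec[[4]]$Sa, p$mconv_W, dlogits, 3L, 1L)
  g$mconv_W <- cb$gW; g$mconv_b <- cb$gb
  gcur <- cb$gx
  gE <- vector("list", 4L)

  for (j in 4:1) {
    dc <- cache$dec[[j]]
    nms <- sprintf("dec%d_bns", j)
    bs <- bnrelu_bwd(gcur, dc$Sa, dc$bns, p[[paste0(nms, "_gamma")]])
    g[[paste0(nms, "_gamma")]] <- bs$dgamma
    g[[paste0(nms, "_beta")]] <- bs$dbeta
    gS <- bs$dx
    gE[[j]] <- gS
    cbb <- conv_bwd(dc$Ta, p[[sprintf("dec%d_b_W", j)]], gS, 3L, 1L)
    g[[sprintf("dec%d_b_W", j)]] <- cbb$gW
    g[[sprintf("dec%d_b_b", j)]] <- cbb$gb
    if (j <= 3L) {
      cbf <- conv_bwd(dc$Tt, p[[sprintf("dec%d_f_W", j)]], gS, 1L, 0L)
      g[[sprintf("dec%d_f_W", j)]] <- cbf$gW
      gT_proj <- cbf$gx
    } else {
      gT_proj <- gS
    }
    nma <- sprintf("dec%d_bna", j)
    ba <- bnrelu_bwd(cbb$gx, dc$Ta, dc$bna, p[[paste0(nma, "_gamma")]])
    g[[paste0(nma, "_gamma")]] <- ba$dgamma
    g[[paste0(nma, "_beta")]] <- ba$dbeta
    gT <- ba$dx + gT_proj
    cba <- conv_bwd(dc$up, p[[sprintf("dec%d_a_W", j)]], gT, 3L, 1L)
    g[[sprintf("dec%d_a_W", j)]] <- cba$gW
    g[[sprintf("dec%d_a_b", j)]] <- cba$gb
    gcur <- cpp_pool_gather(cba$gx, cache$enc[[5L - j]]$idx)
  }

  gpool <- vector("list", 4L)
  gpool[[4L]] <- gcur
  for (i in 4:1) {
    gi <- gpool[[i]]
    if (i <= 3L) gi <- gi + gE[[4L - i]]   # outer-stream contribution
    ec <- cache$enc[[i]]
    pd <- ec$pre_dim
    gRa <- cpp_pool_scatter(gi, ec$idx, pd[1], pd[2])
    nms <- sprintf("enc%d_bns", i)
    bs <- bnrelu_bwd(gRa, ec$Ra, ec$bns, p[[paste0(nms, "_gamma")]])
    g[[paste0(nms, "_gamma")]] <- bs$dgamma
    g[[paste0(nms, "_beta")]] <- bs$dbeta
    gR <- bs$dx
    cbb <- conv_bwd(ec$Ta, p[[sprintf("enc%d_b_W", i)]], gR, 3L, 1L)
    g[[sprintf("enc%d_b_W", i)]] <- cbb$gW
    g[[sprintf("enc%d_b_b", i)]] <- cbb$gb
    gTa <- cbb$gx
    if (i == 1L) gTa <- gTa + gE[[4L]]     # first-conv outer stream
    nma <- sprintf("enc%d_bna", i)
    ba <- bnrelu_bwd(gTa, ec$Ta, ec$bna, p[[paste0(nma, "_gamma")]])
    g[[paste0(nma, "_gamma")]] <- ba$dgamma
    g[[paste0(nma, "_beta")]] <- ba$dbeta
    gT <- ba$dx + gR                       # inner identity stream
    cba <- conv_bwd(ec$x_in, p[[sprintf("enc%d_a_W", i)]], gT, 3L, 1L)
    g[[sprintf("enc%d_a_W", i)]] <- cba$gW
    g[[sprintf("enc%d_a_b", i)]] <- cba$gb
    if (i > 1L) gpool[[i - 1L]] <- cba$gx
  }
  g
}

#' Segment an image with a trained network
#'
#' Runs a forward pass in inference mode (batch-norm running
#' statistics) and returns the per-pixel argmax class mask.
#'
#' @param net A (typically trained) `mesh_net`.
#' @param image `[H, W, C]` array matching the network's input
#'   channels; a grayscale `[H, W, 1]` image is replicated if the
#'   network expects 3 channels.
#' @param return_probs Also return the probability tensor?
#' @return An integer `[H, W]` class mask, or a list
#'   `list(mask, probs)` when `return_probs = TRUE`.
#' @export
segment_image <- function(net, image, return_probs = FALSE) {
  image <- as_image(image)
  if (dim(image)[3] == 1L && net$spec$input_channels == 3L) {
    image <- array(image, c(dim(image)[1:2], 3L))
  }
  fw <- forward_mesh(net, image, train = FALSE)
  pr <- fw$probs
  d <- dim(pr)
  mask <- matrix(0L, d[1], d[2])
  best <- pr[, , 1L, 1L]
  for (k in seq_len(d[3])[-1L]) {
    pk <- pr[, , k, 1L]
    upd <- pk > best
    mask[upd] <- k - 1L
    best[upd] <- pk[upd]
  }
  if (return_probs) list(mask = mask, probs = pr) else mask
}
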