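#' Training configuration
#'
#' Defaults follow the training recipe the network was designed with:
#' Adam with initial learning rate 0.0003, 20 epochs, minibatches of 17
#' images, and global L2 gradient clipping at threshold 6 with epsilon
#' 1e-6. Adam moments are the conventional beta1 = 0.9, beta2 = 0.999.
#'
#' @param learning_rate Adam step size.
#' @param epochs Number of passes over the training set.
#' @param minibatch Images per gradient step (must not exceed the
#'   training-set size).
#' @param grad_threshold Global L2 norm ceiling for [clip_gradients()].
#' @param grad_norm_epsilon Epsilon of the clipping rescale.
#' @param adam_beta1,adam_beta2,adam_epsilon Adam moment settings.
#' @param seed Integer seed for shuffling (weight initialization is
#'   seeded in [assemble()]).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 3e-4, epochs = 20L,
                         minibatch = 17L, grad_threshold = 6,
                         grad_norm_epsilon = 1e-6, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, adam_epsilon = 1e-8,
                         seed = 1L) {
  cfg <- list(learning_rate = learning_rate, epochs = as.integer(epochs),
              minibatch = as.integer(minibatch),
              grad_threshold = grad_threshold,
              grad_norm_epsilon = grad_norm_epsilon,
              adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
              adam_epsilon = adam_epsilon, seed = as.integer(seed))
  if (cfg$learning_rate < 0 || cfg$epochs < 1 || cfg$minibatch < 1 ||
      cfg$grad_threshold <= 0 || cfg$grad_norm_epsilon <= 0) {
    stopf("train_config values must be positive (learning_rate may be 0)")
  }
  structure(cfg, class = "train_config")
}

#' Median-frequency-balanced class weights
#'
#' For every class `c`, the frequency `f_c` is the total number of
#' pixels of class `c` divided by the total pixel count of the images
#' in which class `c` appears. The weight is
#' `w_c = median(f) / f_c` over the classes present; classes absent
#' from the whole set get weight 0. Rare classes (clavicles) thereby
#' receive weights above 1 and dominant classes below 1, balancing the
#' cross-entropy loss.
#'
#' @param masks List of integer `[H, W]` masks.
#' @param num_classes Number of classes.
#' @return A `class_weights` list with `weights` and `freq` vectors of
#'   length `num_classes`.
#' @export
median_frequency_weights <- function(masks, num_classes = 4L) {
  if (length(masks) == 0) stopf("mask list is empty")
  masks <- lapply(masks, as_mask)
  counts <- numeric(num_classes)
  denom <- numeric(num_classes)
  for (m in masks) {
    if (any(m < 0L | m >= num_classes)) {
      stopf("mask labels outside 0:%d", num_classes - 1L)
    }
    tab <- tabulate(as.vector(m) + 1L, nbins = num_classes)
    counts <- counts + tab
    denom <- denom + ifelse(tab > 0, length(m), 0)
  }
  present <- counts > 0
  freq <- ifelse(present, counts / denom, NA_real_)
  med <- median(freq[present])
  weights <- ifelse(present, med / freq, 0)
  structure(list(weights = weights, freq = freq), class = "class_weights")
}

#' Clip gradients by global L2 norm
#'
#' Computes the global L2 norm `g` over all gradient tensors; if it
#' exceeds `threshold`, every gradient is scaled by
#' `threshold / (g + epsilon)`, otherwise the gradients pass through
#' unchanged.
#'
#' @param gradients Named list of numeric tensors.
#' @param threshold Norm ceiling (default 6).
#' @param epsilon Stabilizer of the rescale (default 1e-6).
#' @return The (possibly rescaled) gradient list.
#' @export
clip_gradients <- function(gradients, threshold = 6, epsilon = 1e-6) {
  if (threshold <= 0) stopf("threshold must be positive")
  g <- sqrt(sum(vapply(gradients, function(t) sum(t^2), numeric(1))))
  if (g <= threshold) return(gradients)
  s <- threshold / (g + epsilon)
  lapply(gradients, function(t) t * s)
}

# Stack samples into the [H, W, C, B] / [H, W, B] minibatch tensors.
stack_batch <- function(samples, channels) {
  d <- dim(as_image(samples[[1]]$image))
  B <- length(samples)
  x <- array(0, c(d[1], d[2], channels, B))
  y <- array(0L, c(d[1], d[2], B))
  for (b in seq_len(B)) {
    img <- as_image(samples[[b]]$image)
    if (!identical(dim(img)[1:2], d[1:2])) {
      stopf("all training images must share dimensions (%s vs %s)",
            paste(d[1:2], collapse = "x"),
            paste(dim(img)[1:2], collapse = "x"))
    }
    if (dim(img)[3] == 1L && channels == 3L) {
      img <- array(img, c(d[1], d[2], 3L))
    }
    if (dim(img)[3] != channels) {
      stopf("image has %d channels, network expects %d",
            dim(img)[3], channels)
    }
    x[, , , b] <- img
    y[, , b] <- as_mask(samples[[b]]$mask)
  }
  list(x = x, y = y)
}

#' Train a residual-mesh network
#'
#' From-scratch training with Adam, median-frequency-balanced
#' cross-entropy, and global L2 gradient clipping. Each epoch shuffles
#' the set and runs `ceiling(n / minibatch)` steps; minibatch loss and
#' pixel accuracy are logged per step and averaged per epoch. Given a
#' fixed seed (and fixed BLAS threading) the run is deterministic.
#'
#' @param net An [assemble()]d `mesh_net`.
#' @param dataset An [build_training_set()] result or a plain list of
#'   `list(image =, mask =)` samples (e.g. from [generate_dataset()]).
#' @param config A [train_config()].
#' @param class_weights Optional [median_frequency_weights()] result;
#'   computed from the training masks when omitted.
#' @param verbose Print a line per epoch?
#' @return A `mesh_fit` list: the trained `net`, the per-step `log`
#'   and per-epoch `epoch_log` data frames, `config` and
#'   `class_weights`.
#' @export
train <- function(net, dataset, config = train_config(),
                  class_weights = NULL, verbose = FALSE) {
  samples <- if (inherits(dataset, "augmented_set")) dataset$pairs else dataset
  n <- length(samples)
  if (n == 0) stopf("training dataset is empty")
  if (config$minibatch > n) {
    stopf("minibatch (%d) exceeds the training-set size (%d)",
          config$minibatch, n)
  }
  K <- net$spec$num_classes
  masks <- lapply(samples, `[[`, "mask")
  bad <- unlist(lapply(masks, function(m) unique(m[m >= K | m < 0])))
  if (length(bad)) {
    stopf("mask labels %s are incompatible with num_classes = %d",
          paste(sort(unique(bad)), collapse = ", "), K)
  }
  if (is.null(class_weights)) {
    class_weights <- median_frequency_weights(masks, K)
  }
  w <- class_weights$weights

  adam_m <- lapply(net$params, function(t) t * 0)
  adam_v <- adam_m
  t_step <- 0L
  log_rows <- list()

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$minibatch)
      for (s in starts) {
        sel <- ord[s:min(s + config$minibatch - 1L, n)]
        batch <- stack_batch(samples[sel], net$spec$input_channels)
        fw <- forward_mesh(net, batch$x, train = TRUE, keep_cache = TRUE)
        net$running <- fw$running
        loss <- weighted_cross_entropy(fw$probs, batch$y, w)
        acc <- pixel_accuracy(fw$probs, batch$y)
        dlogits <- wce_logit_grad(fw$probs, batch$y, w)
        grads <- backward_mesh(net, fw$cache, dlogits)
        grads <- clip_gradients(grads, config$grad_threshold,
                                config$grad_norm_epsilon)
        t_step <- t_step + 1L
        b1 <- config$adam_beta1; b2 <- config$adam_beta2
        corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
        for (nm in names(net$params)) {
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * grads[[nm]]
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * grads[[nm]]^2
          net$params[[nm]] <- net$params[[nm]] -
            config$learning_rate * (adam_m[[nm]] / corr1) /
            (sqrt(adam_v[[nm]] / corr2) + config$adam_epsilon)
        }
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(epoch = epoch, step = t_step, loss = loss, acc = acc)
      }
      if (verbose) {
        ep <- do.call(rbind, log_rows)
        ep <- ep[ep$epoch == epoch, ]
        message(sprintf("epoch %d: loss %.4f, accuracy %.4f",
                        epoch, mean(ep$loss), mean(ep$acc)))
      }
    }
  })

  log <- do.call(rbind, log_rows)
  epoch_log <- do.call(rbind, lapply(split(log, log$epoch), function(e) {
    data.frame(epoch = e$epoch[1], loss = mean(e$loss), acc = mean(e$acc))
  }))
  rownames(epoch_log) <- NULL
  structure(list(net = net, log = log, epoch_log = epoch_log,
                 config = config, class_weights = class_weights),
            class = "mesh_fit")
}

#' @export
print.mesh_fit <- function(x, ...) {
  last <- x$epoch_log[nrow(x$epoch_log), ]
  cat(sprintf("trained network: %d epochs, %d steps; final loss %.4f, accuracy %.4f\n",
              nrow(x$epoch_log), nrow(x$log), last$loss, last$acc))
  invisible(x)
}

#' Save / load a checkpoint
#'
#' A checkpoint is a single file holding the weights, batch-norm
#' running statistics, the embedded network spec, and (for a fit) the
#' training config and epoch log.
#'
#' @param x A `mesh_net` or `mesh_fit`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly;
#'   `load_checkpoint` returns the restored object.
#' @export
save_checkpoint <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Spec round trip through a plain-text config
#'
#' Writes/reads the declarative network description as `key: value`
#' lines (width multiplier, class count, input channels).
#'
#' @param spec A `mesh_spec`.
#' @param path Text file path.
#' @return `read_spec_config` returns the reconstructed `mesh_spec`.
#' @export
write_spec_config <- function(spec, path) {
  writeLines(c(sprintf("width_multiplier: %.10g", spec$width_multiplier),
               sprintf("num_classes: %d", spec$num_classes),
               sprintf("input_channels: %d", spec$input_channels)),
             path)
  invisible(path)
}

#' @rdname write_spec_config
#' @export
read_spec_config <- function(path) {
  kv <- read_key_values(path)
  make_spec(width_multiplier = as.numeric(kv[["width_multiplier"]]),
            num_classes = as.integer(kv[["num_classes"]]),
            input_channels = as.integer(kv[["input_channels"]]))
}

read_key_values <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ":", fixed = TRUE)
  setNames(lapply(parts, function(p) trimws(paste(p[-1], collapse = ":"))),
           vapply(parts, function(p) trimws(p[1]), character(1)))
}

#' Write the per-step training log as CSV
#'
#' @param fit A `mesh_fit`.
#' @param path Output CSV path.
#' @export
write_training_log <- function(fit, path) {
  write.csv(fit$log, path, row.names = FALSE)
  invisible(path)
}
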