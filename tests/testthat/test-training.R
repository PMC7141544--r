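test_that("median frequency balancing matches hand-computed frequencies", {
  # a single one-class mask: median of a singleton gives weight 1
  w <- median_frequency_weights(list(matrix(0L, 4, 4)), num_classes = 4L)
  expect_equal(w$weights, c(1, 0, 0, 0))

  # frequencies 0.75 / 0.25: median 0.5 -> weights 2/3 and 2
  m <- matrix(0L, 2, 2); m[1, 1] <- 1L
  m2 <- matrix(c(0L, 0L, 0L, 1L), 2, 2)
  w2 <- median_frequency_weights(list(m, m2), num_classes = 2L)
  expect_equal(w2$freq, c(0.75, 0.25))
  expect_equal(w2$weights, c(2 / 3, 2))

  # uniform class frequencies give unit weights
  mu <- matrix(rep(0:3, each = 4), 4, 4)
  expect_equal(median_frequency_weights(list(mu))$weights, rep(1, 4))

  expect_error(median_frequency_weights(list()), "empty")
})

test_that("median frequency weights equal a brute-force tally oracle", {
  masks <- lapply(1:4, function(i) random_mask(6, 5, 3, seed = i))
  got <- median_frequency_weights(masks, num_classes = 3L)
  # oracle: explicit per-image loops
  f <- numeric(3)
  for (c in 0:2) {
    pix <- 0; tot <- 0
    for (m in masks) {
      n <- sum(m == c)
      if (n > 0) { pix <- pix + n; tot <- tot + length(m) }
    }
    f[c + 1] <- pix / tot
  }
  expect_equal(got$freq, f)
  expect_equal(got$weights, median(f) / f)
})

test_that("weighted cross-entropy has its closed forms and a loop oracle", {
  h <- 3; w <- 3; K <- 4
  target <- random_mask(h, w, K, seed = 2)
  onehot <- array(0, c(h, w, K))
  for (r in 1:h) for (cc in 1:w) onehot[r, cc, target[r, cc] + 1] <- 1
  expect_equal(weighted_cross_entropy(onehot, target, rep(1, K)), 0)

  unif <- array(1 / K, c(h, w, K))
  expect_equal(weighted_cross_entropy(unif, target, rep(1, K)), log(4))

  probs <- cxrmesh:::with_seed(5, array(runif(h * w * K), c(h, w, K)))
  for (r in 1:h) for (cc in 1:w) {
    probs[r, cc, ] <- probs[r, cc, ] / sum(probs[r, cc, ])
  }
  wts <- c(0.5, 2, 1, 3)
  oracle <- 0
  for (r in 1:h) for (cc in 1:w) {
    y <- target[r, cc]
    oracle <- oracle - wts[y + 1] * log(probs[r, cc, y + 1])
  }
  oracle <- oracle / (h * w)
  expect_equal(weighted_cross_entropy(probs, target, wts), oracle)
  expect_error(weighted_cross_entropy(probs, target[1:2, ], wts),
               "incompatible")
})

test_that("gradient clipping rescales only above the global-norm threshold", {
  g <- list(a = c(1, 2), b = matrix(2, 1, 1))   # norm 3
  expect_identical(clip_gradients(g, threshold = 6), g)

  g2 <- list(a = c(12))                          # norm 12
  out <- clip_gradients(g2, threshold = 6, epsilon = 1e-6)
  expect_equal(out$a, 12 * 6 / (12 + 1e-6))      # hand computation

  big <- list(a = rnorm(50) * 10, b = rnorm(20) * 10)
  out2 <- clip_gradients(big, threshold = 6)
  norm2 <- sqrt(sum(unlist(out2)^2))
  expect_lte(norm2, 6 + 1e-9)
  expect_error(clip_gradients(g, threshold = 0), "positive")
})

test_that("a zero learning rate leaves the weights untouched", {
  ds <- generate_dataset(small_phantom_config(), 4L, seed = 2L)
  net <- assemble(tiny_spec(), seed = 1)
  fit <- train(net, ds, train_config(learning_rate = 0, epochs = 1L,
                                     minibatch = 2L, seed = 1L))
  expect_equal(fit$net$params, net$params)
})

test_that("seeded training is reproducible and the loss trends down", {
  ds <- generate_dataset(small_phantom_config(), 12L, seed = 7L)
  cfg <- train_config(epochs = 5L, minibatch = 6L, seed = 21L)
  fit <- train(assemble(tiny_spec(), seed = 2), ds, cfg)
  expect_identical(nrow(fit$log), 10L)           # 5 epochs x 2 steps
  expect_lt(fit$epoch_log$loss[5], fit$epoch_log$loss[1])
  fit2 <- train(assemble(tiny_spec(), seed = 2), ds, cfg)
  expect_equal(fit$net$params, fit2$net$params)
  expect_equal(fit$log, fit2$log)
})

test_that("training rejects impossible inputs", {
  ds <- generate_dataset(small_phantom_config(), 3L, seed = 1L)
  net <- assemble(tiny_spec(), seed = 1)
  expect_error(train(net, list(), train_config()), "empty")
  expect_error(train(net, ds, train_config(minibatch = 17L)),
               "exceeds the training-set size")
  net2 <- assemble(tiny_spec(num_classes = 2), seed = 1)
  expect_error(train(net2, ds, train_config(minibatch = 2L)),
               "incompatible with num_classes")
})
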