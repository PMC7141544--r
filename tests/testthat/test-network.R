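test_that("spec widths follow the doubling chain under any multiplier", {
  expect_identical(make_spec(variant = 1)$encoder_widths,
                   c(64L, 128L, 256L, 512L))
  expect_identical(make_spec(variant = 2)$encoder_widths,
                   c(32L, 64L, 128L, 256L))
  expect_identical(make_spec(width_multiplier = 0.125)$encoder_widths,
                   c(8L, 16L, 32L, 64L))
  expect_error(make_spec(width_multiplier = 0), "positive")
  expect_error(make_spec(num_classes = 1), "num_classes")
  # decoder: first conv keeps width, second halves down the chain
  dw <- make_spec(variant = 1)$decoder_widths
  expect_identical(unname(vapply(dw, `[[`, integer(1), 1)),
                   c(512L, 256L, 128L, 64L))
  expect_identical(unname(vapply(dw, `[[`, integer(1), 2)),
                   c(256L, 128L, 64L, 64L))
})

test_that("assembly produces 17 3x3 convolutions, 3 projections, 4 pool pairs", {
  net <- assemble(make_spec(width_multiplier = 0.0625))
  expect_identical(sum(net$layers$kind == "conv3"), 17L)
  expect_identical(sum(net$layers$kind == "conv1"), 3L)
  expect_identical(sum(net$layers$kind == "maxpool"), 4L)
  expect_identical(sum(net$layers$kind == "unpool"), 4L)
  # a malformed spec fails at assembly, not at forward time
  bad <- make_spec(width_multiplier = 0.0625)
  bad$decoder_widths[[2]][2] <- 99L
  expect_error(assemble(bad), "channel compatibility")
})

test_that("the residual census is 12 paths, 9 identity, 3 nonidentity", {
  for (m in c(1, 0.5, 0.125)) {
    cen <- census_residual_paths(assemble(make_spec(width_multiplier = m)))
    expect_identical(cen$total, 12L)
    expect_identical(cen$identity, 9L)
    expect_identical(cen$nonidentity, 3L)
    expect_identical(sum(cen$paths$stream == "OIS"), 4L)
    expect_identical(sum(cen$paths$stream == "INIS"), 3L)
  }
})

test_that("parameter counts match closed-form layer sums and scale ~ m^2", {
  v1 <- assemble(make_spec(variant = 1))
  # first conv: 3x3, 3 -> 64 channels, with bias
  expect_identical(length(v1$params$enc1_a_W) + length(v1$params$enc1_a_b),
                   1792L)
  # layer table agrees with the tensor store
  expect_equal(sum(v1$layers$n_params), count_parameters(v1))
  c1 <- count_parameters(v1)
  for (m in c(0.5, 0.25)) {
    cm <- count_parameters(assemble(make_spec(width_multiplier = m)))
    expect_gte(cm / c1, m^2 * 0.95)
    expect_lte(cm / c1, m^2 * 1.10)
  }
})

test_that("max-unpooling restores retained maxima to their coordinates", {
  # 4x4 toy plane, hand-picked maxima
  x <- array(0, c(4, 4, 1, 1))
  x[1, 2, 1, 1] <- 5   # window (1:2, 1:2) max at (1,2)
  x[2, 3, 1, 1] <- 7   # window (1:2, 3:4) max at (2,3)
  x[4, 1, 1, 1] <- 3   # window (3:4, 1:2) max at (4,1)
  x[3, 4, 1, 1] <- 9   # window (3:4, 3:4) max at (3,4)
  pl <- cxrmesh:::cpp_maxpool(x)
  expect_equal(as.vector(pl$y), c(5, 3, 7, 9))
  up <- cxrmesh:::cpp_pool_scatter(pl$y, pl$idx, 4L, 4L)
  expect_equal(up, x)
  # gather is the adjoint: it reads back exactly the scattered values
  expect_equal(cxrmesh:::cpp_pool_gather(up, pl$idx), pl$y)
})

test_that("forward pass preserves spatial size and halves four times", {
  net <- assemble(tiny_spec(), seed = 4)
  img <- array(runif(64 * 64), c(64, 64, 1))
  fw <- cxrmesh:::forward_mesh(net, img)
  expect_identical(unname(fw$shapes$deepest), c(4L, 4L))
  expect_identical(dim(fw$probs), c(64L, 64L, 4L, 1L))
  sums <- apply(fw$probs, c(1, 2, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  # odd sizes floor at each pooling and are restored exactly
  img2 <- array(runif(50 * 46), c(50, 46, 1))
  fw2 <- cxrmesh:::forward_mesh(net, img2)
  expect_identical(unname(fw2$shapes$deepest), c(3L, 2L))
  expect_identical(dim(fw2$probs)[1:2], c(50L, 46L))
  expect_error(cxrmesh:::forward_mesh(net, array(0, c(8, 8, 1))),
               "too small")
  expect_error(cxrmesh:::forward_mesh(net, array(0, c(32, 32, 3))),
               "channels")
})

test_that("analytic gradients match central finite differences", {
  sp <- tiny_spec(num_classes = 3)
  net <- assemble(sp, seed = 3)
  x <- cxrmesh:::with_seed(8, array(runif(16 * 16 * 2), c(16, 16, 1, 2)))
  y <- random_mask(16, 32, 3, seed = 9)
  dim(y) <- c(16, 16, 2)
  w <- c(1, 1.5, 0.7)
  loss_fn <- function(nn) {
    fw <- cxrmesh:::forward_mesh(nn, x, train = TRUE)
    weighted_cross_entropy(fw$probs, y, w)
  }
  fw <- cxrmesh:::forward_mesh(net, x, train = TRUE, keep_cache = TRUE)
  g <- cxrmesh:::backward_mesh(net, fw$cache,
                               cxrmesh:::wce_logit_grad(fw$probs, y, w))
  eps <- 1e-5
  # probe tensors covering every stream type in the mesh
  probes <- c("enc1_a_W", "enc3_b_W", "enc2_bns_gamma", "dec1_a_W",
              "dec2_f_W", "dec4_b_W", "dec3_bna_beta", "mconv_W")
  for (nm in probes) {
    i <- cxrmesh:::with_seed(1, sample(length(net$params[[nm]]), 1))
    np <- net; np$params[[nm]][i] <- np$params[[nm]][i] + eps
    nmn <- net; nmn$params[[nm]][i] <- nmn$params[[nm]][i] - eps
    num <- (loss_fn(np) - loss_fn(nmn)) / (2 * eps)
    expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                 label = sprintf("gradient of %s", nm))
  }
})

test_that("one backward pass reaches every trainable tensor through the mesh", {
  net <- assemble(tiny_spec(), seed = 5)
  x <- cxrmesh:::with_seed(2, array(runif(16 * 16), c(16, 16, 1, 1)))
  y <- random_mask(16, 16, 4, seed = 3)
  dim(y) <- c(16, 16, 1)
  fw <- cxrmesh:::forward_mesh(net, x, train = TRUE, keep_cache = TRUE)
  g <- cxrmesh:::backward_mesh(net, fw$cache,
                               cxrmesh:::wce_logit_grad(fw$probs, y,
                                                        rep(1, 4)))
  expect_setequal(names(g), names(net$params))
  nonzero <- vapply(g, function(t) any(t != 0), logical(1))
  expect_true(all(nonzero))
})

test_that("spec and checkpoint round-trip through their file formats", {
  sp <- make_spec(width_multiplier = 0.25, num_classes = 2,
                  input_channels = 1)
  f <- withr::local_tempfile(fileext = ".txt")
  write_spec_config(sp, f)
  expect_equal(read_spec_config(f), sp)

  net <- assemble(tiny_spec(), seed = 6)
  ck <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, ck)
  back <- load_checkpoint(ck)
  expect_equal(back$params, net$params)
  expect_equal(back$spec, net$spec)
})
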