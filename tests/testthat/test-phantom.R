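test_that("phantom generation is deterministic and labels are well formed", {
  cfg <- small_phantom_config(seed = 7L)
  s1 <- generate_phantom(cfg)
  s2 <- generate_phantom(cfg)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)

  expect_identical(dim(s1$image)[1:2], dim(s1$mask))
  expect_true(all(s1$mask %in% 0:3))
  expect_true(all(s1$image >= 0 & s1$image <= 1))
  # heart is a single connected region
  heart <- s1$mask == 2L
  expect_identical(cxrmesh:::largest_cc(heart), heart)
})

test_that("prescribed extents fix the ground-truth CTR by construction", {
  cfg <- phantom_config(heart_extent = 100L, thorax_extent = 250L,
                        width = 256L, height = 256L)
  s <- generate_phantom(cfg)
  expect_equal(s$true_ctr, 0.4)
  # round trip: the CTR computed from the mask is exactly the truth
  expect_identical(compute_ctr(s$mask)$ctr, s$true_ctr)
  expect_identical(compute_ctr(s$mask)$AB, 100L)
  expect_identical(compute_ctr(s$mask)$CD, 250L)
})

test_that("clavicles can be switched off and contrast sets the heart/lung gap", {
  s <- generate_phantom(small_phantom_config(clavicles_present = FALSE))
  expect_false(any(s$mask == 3L))
  s2 <- generate_phantom(small_phantom_config(clavicles_present = TRUE))
  expect_true(any(s2$mask == 3L))

  sq <- generate_phantom(small_phantom_config(noise_sd = 0, contrast = 0.2))
  heart_val <- unique(sq$image[, , 1][sq$mask == 2L])
  lung_val <- unique(sq$image[, , 1][sq$mask == 1L])
  expect_length(heart_val, 1L)
  expect_equal(heart_val - lung_val, 0.2)
})

test_that("invalid phantom configs are rejected with descriptive errors", {
  expect_error(phantom_config(heart_extent = 300L, thorax_extent = 200L),
               "heart_extent")
  expect_error(phantom_config(thorax_extent = 256L, width = 256L),
               "thorax_extent")
  expect_error(phantom_config(height = 16L), "at least 32")
  expect_error(phantom_config(noise_sd = -0.1), "noise_sd")
})

test_that("dataset generation is reproducible and perturbs geometry", {
  cfg <- small_phantom_config()
  expect_identical(generate_dataset(cfg, 0L), list())
  d1 <- generate_dataset(cfg, 10L, seed = 3L)
  d2 <- generate_dataset(cfg, 10L, seed = 3L)
  expect_length(d1, 10L)
  expect_identical(d1, d2)
  ctrs <- vapply(d1, `[[`, numeric(1), "true_ctr")
  expect_gt(length(unique(ctrs)), 5L)         # geometry actually varies
  for (s in d1) {
    expect_true(all(s$mask %in% 0:3))
    expect_identical(compute_ctr(s$mask)$ctr, s$true_ctr)
  }
})

test_that("phantom datasets round-trip through the paired-PNG layout", {
  dir <- withr::local_tempdir()
  d <- generate_dataset(small_phantom_config(), 3L, seed = 5L)
  manifest <- write_phantom_dataset(d, dir)
  expect_identical(nrow(manifest), 3L)
  back <- read_dataset(dir, size = NULL)
  for (i in 1:3) {
    expect_identical(back[[i]]$mask, d[[i]]$mask)
    expect_equal(back[[i]]$true_ctr, d[[i]]$true_ctr)
  }
})
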