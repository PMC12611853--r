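test_that("phantom generation is deterministic and respects mask invariants", {
  cfg <- phantom_config(image_size = 64L, seed = 9L)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$nodule_mask, b$nodule_mask)
  expect_true(all(a$nodule_mask %in% c(0L, 1L)))
  expect_true(all(a$lung_mask %in% c(0L, 1L)))
  # nodules lie strictly inside the lung fields
  expect_true(all(a$nodule_mask[a$lung_mask == 0L] == 0L))
})

test_that("nodule count matches the 8-connected component count", {
  cfg <- phantom_config(image_size = 96L, n_nodules_range = c(3L, 3L), seed = 21L)
  p <- generate_phantom(cfg)
  expect_equal(p$n_nodules, 3L)
  expect_equal(flood_count(p$nodule_mask), 3L)
  empty <- generate_phantom(phantom_config(image_size = 64L,
                                           n_nodules_range = c(0L, 0L), seed = 2L))
  expect_true(all(empty$nodule_mask == 0L))
})

test_that("noise-free phantoms take exactly the four configured intensities", {
  cfg <- phantom_config(image_size = 64L, noise_sigma = 0, seed = 5L,
                        n_nodules_range = c(2L, 2L))
  p <- generate_phantom(cfg)
  expect_setequal(unique(as.vector(p$image)),
                  c(cfg$background_intensity, cfg$lung_intensity,
                    cfg$nodule_intensity, cfg$body_intensity))
})

test_that("degenerate geometry is rejected with a sizing error", {
  expect_error(phantom_config(image_size = 16L), "image_size")
  expect_error(
    generate_phantom(phantom_config(image_size = 32L,
                                    nodule_radius_range = c(6, 8),
                                    n_nodules_range = c(1L, 1L))),
    "cannot fit")
  expect_error(phantom_config(lung_intensity = 0.9), "intensities")
})

test_that("dataset splits partition the samples with rounded-fraction sizes", {
  ds <- generate_phantom_dataset(10, phantom_config(image_size = 64L, seed = 1L))
  expect_equal(lengths(ds$indices[c("train", "val", "test")]),
               c(train = 8L, val = 1L, test = 1L))
  for (n in c(10, 37, 100)) {
    sp <- split_dataset(n, c(0.8, 0.1, 0.1), seed = 3L)
    all_idx <- c(sp$train, sp$val, sp$test)
    expect_setequal(all_idx, seq_len(n))
    expect_equal(length(all_idx), n)  # pairwise disjoint
    sp2 <- split_dataset(n, c(0.8, 0.1, 0.1), seed = 3L)
    expect_identical(sp, sp2)
  }
  expect_error(split_dataset(5, c(0.8, 0.1, 0.1)), "at least one")
})

test_that("phantom datasets reproduce and write PNG pairs with a manifest", {
  cfg <- phantom_config(image_size = 64L, seed = 77L)
  d1 <- generate_phantom_dataset(12, cfg)
  d2 <- generate_phantom_dataset(12, cfg)
  expect_identical(d1$indices, d2$indices)
  expect_identical(d1$train[[1]]$image, d2$train[[1]]$image)
  dir <- withr::local_tempdir()
  write_phantom_dataset(d1$test, dir)
  man <- read.delim(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(man), length(d1$test))
  expect_true(all(file.exists(file.path(dir, man$image))))
  rt <- read_slice(file.path(dir, man$nodule_mask[1]))
  expect_equal(unname(rt$image), d1$test[[1]]$nodule_mask, ignore_attr = TRUE)
})
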