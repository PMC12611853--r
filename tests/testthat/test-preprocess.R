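test_that("standardization gives zero mean, unit population variance", {
  set.seed(1)
  x <- matrix(runif(64, 10, 50), 8, 8)
  z <- standardize(x)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-6)
  # affine invariance and the hand-computed 2x2 case
  expect_equal(standardize(3 * x + 7), z, tolerance = 1e-12)
  expect_equal(standardize(matrix(c(0, 0, 2, 2), 2, 2)),
               matrix(c(-1, -1, 1, 1), 2, 2))
  expect_error(standardize(matrix(5, 4, 4)), "degenerate")
})

test_that("median filter matches an exhaustive window oracle and handles borders", {
  img <- matrix(2, 7, 7)
  img[4, 4] <- 90  # isolated bright pixel
  expect_equal(median_filter(img, 3L), matrix(2, 7, 7))
  expect_identical(median_filter(img, 1L), img)
  expect_error(median_filter(img, 4L), "odd")
  # exhaustive oracle with reflection padding on a random image
  set.seed(2)
  x <- matrix(rnorm(36), 6, 6)
  ref <- matrix(0, 6, 6)
  refl <- function(i, n) { while (i < 1 || i > n) { if (i < 1) i <- 1 - i; if (i > n) i <- 2 * n + 1 - i }; i }
  for (i in 1:6) for (j in 1:6) {
    win <- numeric(0)
    for (di in -1:1) for (dj in -1:1) {
      win <- c(win, x[refl(i + di, 6), refl(j + dj, 6)])
    }
    ref[i, j] <- median(win)
  }
  expect_equal(median_filter(x, 3L), ref, tolerance = 1e-12)
})

test_that("anisotropic diffusion preserves constants and reduces variance", {
  const <- matrix(3.5, 10, 10)
  expect_equal(anisotropic_diffusion(const, diffusion_params(25)), const)
  x <- matrix(rnorm(400), 20, 20)
  expect_identical(anisotropic_diffusion(x, diffusion_params(0)), x)
  for (s in 1:10) {
    set.seed(s)
    y <- matrix(rnorm(256), 16, 16)
    for (cond in c("exponential", "rational")) {
      out <- anisotropic_diffusion(y, diffusion_params(8, kappa = 2, conduction = cond))
      expect_lte(var(as.vector(out)), var(as.vector(y)))
    }
  }
  expect_error(diffusion_params(gamma = 0.3), "stability")
  expect_error(diffusion_params(kappa = 0), "kappa")
})

test_that("k-means thresholding labels the dark cluster on a two-level image", {
  img <- matrix(200, 12, 12)
  img[3:6, 3:6] <- 10
  mask <- kmeans_threshold(img, k = 2L, seed = 1L)
  expect_true(all(mask %in% c(0L, 1L)))
  expect_identical(dim(mask), dim(img))
  expect_equal(mask, matrix(as.integer(img == 10), 12, 12))
  # deterministic under the seed, invariant to restarts/orderings
  expect_identical(mask, kmeans_threshold(img, k = 2L, seed = 99L))
  expect_error(kmeans_threshold(matrix(c(1, 1, 1, 2), 2, 2), k = 3L), "distinct")
})

test_that("morphology follows the set-theoretic oracle with outside-as-zero", {
  se <- structuring_element("square", 1L)
  m <- matrix(0L, 5, 5)
  m[2, 2] <- 1L         # isolated pixel
  m[3:5, 3:5] <- 1L     # solid 3x3 block
  opened <- morphological_open(m, se)
  expect_equal(sum(opened[2, 2]), 0)           # isolated pixel removed
  expect_true(all(opened[3:5, 3:5] == 1L))     # block preserved
  set.seed(3)
  for (i in 1:5) {
    r <- random_mask(9, 9)
    expect_identical(erode(r, se), naive_erode(r, se))
    expect_identical(dilate(r, se), naive_dilate(r, se))
    o <- morphological_open(r, se)
    expect_true(all(o <= r))                       # anti-extensive
    expect_identical(morphological_open(o, se), o) # idempotent
    expect_true(all(r <= dilate(r, se)))           # dilation extensive
  }
  expect_identical(morphological_open(matrix(0L, 4, 4), se), matrix(0L, 4, 4))
  expect_error(erode(m, matrix(FALSE, 3, 3)), "empty structuring element")
})

test_that("lung-region selection keeps the two large interior components", {
  m <- matrix(0L, 40, 40)
  m[1, ] <- 1L; m[40, ] <- 1L; m[, 1] <- 1L; m[, 40] <- 1L  # border frame
  m[8:30, 5:15] <- 1L
  m[8:30, 25:35] <- 1L
  m[35, 20] <- 1L  # speck below the area threshold
  sel <- select_lung_regions(m, region_criteria())
  expect_equal(flood_count(sel), 2)
  expect_true(all(sel[8:30, 5:15] == 1L))
  expect_true(all(sel[1, ] == 0L))
  # single interior blob comes back unchanged
  single <- matrix(0L, 30, 30); single[10:20, 10:20] <- 1L
  expect_equal(select_lung_regions(single), single)
  expect_warning(out <- select_lung_regions(matrix(0L, 20, 20)) * 0L, NA)
  expect_true(all(select_lung_regions(matrix(0L, 20, 20)) == 0L))
})

test_that("masking zeroes the complement after the margin dilation", {
  img <- matrix(runif(400), 20, 20)
  ones <- matrix(1L, 20, 20)
  expect_equal(apply_lung_mask(img, ones, NULL), img)
  expect_true(all(apply_lung_mask(img, matrix(0L, 20, 20), NULL) == 0))
  half <- matrix(0L, 20, 20); half[, 1:10] <- 1L
  se <- structuring_element("square", 2L)
  out <- apply_lung_mask(img, half, se)
  grown <- dilate(half, se)
  expect_equal(out, img * grown)
  expect_true(all(out[, 13:20] == 0))
  expect_error(apply_lung_mask(img, ones[1:10, ]), "mismatch")
})

test_that("the full chain recovers the phantom lung fields", {
  p <- generate_phantom(phantom_config(seed = 31L))
  res <- preprocess_slice(p$image)
  expect_identical(dim(res$roi), dim(p$image))
  expect_true(all(res$lung_mask %in% c(0L, 1L)))
  expect_gte(mask_iou(res$lung_mask, p$lung_mask), 0.7)
  expect_error(preprocess_slice(matrix(1, 64, 64)), "standardize")
})

test_that("annotation rasterization fills contours and applies reader votes", {
  sq <- rbind(c(2, 2), c(2, 8), c(8, 8), c(8, 2), c(2, 2))
  one <- list(readers = list(list(id = "r1", contours = list(
    list(slice = 0L, points = sq, equiv_diameter_mm = 10)))))
  m <- rasterize_annotations(one, c(12L, 12L))
  expect_true(all(m[3:9, 3:9] == 1L))
  expect_true(all(m[c(1, 11, 12), ] == 0L))
  # four identical readers agree for any consensus level
  four <- list(readers = lapply(1:4, function(i) list(id = i, contours = list(
    list(slice = 0L, points = sq, equiv_diameter_mm = 10)))))
  expect_equal(rasterize_annotations(four, c(12L, 12L), consensus_fraction = 1), m)
  # 2 of 4 readers marking a region: in at 50%, out at 75%
  two <- four
  two$readers[[3]]$contours <- list()
  two$readers[[4]]$contours <- list()
  at50 <- rasterize_annotations(two, c(12L, 12L), consensus_fraction = 0.5)
  at75 <- rasterize_annotations(two, c(12L, 12L), consensus_fraction = 0.75)
  expect_equal(at50[5, 5], 1L)
  expect_equal(at75[5, 5], 0L)
  # sub-3mm nodules are excluded before voting
  small <- one
  small$readers[[1]]$contours[[1]]$equiv_diameter_mm <- 2.5
  expect_true(all(rasterize_annotations(small, c(12L, 12L)) == 0L))
  open_poly <- list(readers = list(list(id = "r1", contours = list(
    list(slice = 0L, points = sq[1:4, ], equiv_diameter_mm = 10)))))
  expect_error(rasterize_annotations(open_poly, c(12L, 12L)), "unclosed")
})
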