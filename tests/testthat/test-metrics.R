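test_that("confusion counts enumerate pixels correctly", {
  g <- matrix(0L, 5, 5); g[1, 1:3] <- 1L            # |G| = 3
  p <- matrix(0L, 5, 5); p[1, 2:3] <- 1L; p[2, 1:2] <- 1L  # |P| = 4, overlap 2
  cc <- confusion_counts(p, g)
  expect_equal(cc, c(TP = 2, FP = 2, TN = 20, FN = 1))
  expect_equal(sum(cc), 25)
  same <- confusion_counts(g, g)
  expect_equal(unname(same[c("FP", "FN")]), c(0, 0))
  comp <- confusion_counts(1L - g, g)
  expect_equal(unname(comp[c("TP", "TN")]), c(0, 0))
  expect_error(confusion_counts(g * 2L, g), "binary")
})

test_that("metrics implement the overlap definitions and the DSC/IoU identity", {
  m <- compute_metrics(c(TP = 2, FP = 2, TN = 20, FN = 1))
  expect_equal(m$dsc, 4 / 7)
  expect_equal(m$iou, 2 / 5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$accuracy, 22 / 25)
  perfect <- compute_metrics(c(TP = 9, FP = 0, TN = 16, FN = 0))
  expect_equal(unlist(perfect[c("precision", "recall", "dsc", "iou")]),
               c(precision = 1, recall = 1, dsc = 1, iou = 1))
  # empty-vs-empty convention, flagged
  e <- compute_metrics(c(TP = 0, FP = 0, TN = 25, FN = 0))
  expect_equal(e$dsc, 1)
  expect_equal(e$iou, 1)
  expect_true(any(e$degenerate))
  set.seed(4)
  for (i in 1:50) {
    a <- random_mask(8, 8); b <- random_mask(8, 8)
    mm <- compute_metrics(confusion_counts(a, b))
    expect_equal(mm$dsc, 2 * mm$iou / (1 + mm$iou), tolerance = 1e-12)
    expect_true(mm$iou <= mm$dsc + 1e-15 && mm$dsc <= 1 && mm$iou >= 0)
  }
})

test_that("BCE-Dice loss matches closed forms at the anchor points", {
  t <- matrix(0, 8, 8); t[3:4, 3:4] <- 1
  near <- t * (1 - 1e-7) + (1 - t) * 1e-7
  expect_lt(bce_dice_loss(near, t), 1e-5)
  # total disagreement: dice term close to 1
  flipped <- 1 - near
  expect_gt(bce_dice_loss(flipped, t), 0.5 * 1 * 0.9)
  # uniform 0.5 prediction on k positives of N pixels
  k <- sum(t); N <- length(t); s <- 1
  expected <- 0.5 * log(2) + 0.5 * (1 - (k + s) / (0.5 * N + k + s))
  expect_equal(bce_dice_loss(matrix(0.5, 8, 8), t), expected, tolerance = 1e-9)
  expect_error(bce_dice_loss(near, t[1:4, ]), "shapes differ")
  expect_error(bce_dice_loss(near, t, w_bce = 0.7, w_dice = 0.5), "sum to 1")
})

test_that("loss decreases under gradient descent on a separable toy problem", {
  set.seed(5)
  x <- c(rnorm(20, -2), rnorm(20, 2))
  t <- rep(c(0, 1), each = 20)
  wb <- c(0, 0)  # weight, bias
  lossf <- function(wb) bce_dice_loss(plogis(wb[1] * x + wb[2]), t)
  l0 <- lossf(wb)
  for (i in 1:50) {
    eps <- 1e-5
    g <- c((lossf(wb + c(eps, 0)) - lossf(wb - c(eps, 0))) / (2 * eps),
           (lossf(wb + c(0, eps)) - lossf(wb - c(0, eps))) / (2 * eps))
    wb <- wb - 0.5 * g
  }
  expect_lt(lossf(wb), l0)
})
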