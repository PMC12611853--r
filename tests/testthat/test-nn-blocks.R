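test_that("activation registry covers the definitions and rejects unknowns", {
  expect_equal(activation("GELU")$f(0), 0)
  expect_equal(activation("GELU")$f(1), 0.841345, tolerance = 1e-6)
  expect_equal(activation("ReLU")$f(-1), 0)
  expect_equal(activation("LeakyReLU", slope = 0.01)$f(-1), -0.01)
  expect_equal(activation("Swish")$f(2), 2 * plogis(2))
  expect_equal(activation("Mish")$f(2), 2 * tanh(log1p(exp(2))), tolerance = 1e-9)
  expect_equal(activation("SELU")$f(0), 0)
  expect_error(activation("Softsign"), "registered")
  expect_error(activation("LeakyReLU", slope = -1), "slope")
  # monotone non-decreasing on [0, Inf)
  grid <- seq(0, 6, by = 0.05)
  for (nm in activation_names()) {
    v <- activation(nm)$f(grid)
    expect_true(all(diff(v) >= -1e-12), info = nm)
  }
})

test_that("GELU tanh variant tracks the exact erf form", {
  grid <- seq(-5, 5, by = 0.001)
  exact <- activation("GELU")$f(grid)
  approx <- activation("GELU", tanh_approx = TRUE)$f(grid)
  expect_lt(max(abs(exact - approx)), 5e-3)
  # derivative consistency against central differences
  for (nm in activation_names()) {
    a <- activation(nm)
    xs <- seq(-3, 3, by = 0.5) + 0.01
    num <- (a$f(xs + 1e-6) - a$f(xs - 1e-6)) / 2e-6
    expect_equal(a$df(xs), num, tolerance = 1e-4, info = nm)
  }
})

test_that("multi-scale block preserves spatial size and collapses to the 3x3 path", {
  set.seed(11)
  blk <- multiscale_block(3L, 5L)
  x <- array(rnorm(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- block_forward(blk, x, training = TRUE)
  expect_equal(dim(y), c(16, 16, 5, 2))
  # zero the 7x7 branch: its normalized output is zero (beta = 0), so the
  # fused result equals the 1x1-projected 3x3 path alone
  blk$children$path7$children$conv$params$w$v[] <- 0
  y2 <- block_forward(blk, x, training = TRUE)
  p3 <- blk$children$path3$fw(noduleseg:::ag_const(x), training = TRUE)
  zeros <- noduleseg:::ag_const(array(0, dim(p3$v)))
  ref <- blk$children$fuse$fw(noduleseg:::op_concat_c(list(p3, zeros)))
  expect_equal(y2, ref$v, tolerance = 1e-5)
})

test_that("ACB branch sum equals convolution with the fused kernel", {
  x0 <- array(0, c(8, 8, 2, 1))
  blk0 <- acb_block(2L, 3L)
  expect_true(all(abs(blk0$branch_sum(x0)) == 0))
  for (s in 1:20) {
    set.seed(s)
    blk <- acb_block(2L, 4L)
    x <- array(rnorm(12 * 12 * 2 * 2), c(12, 12, 2, 2))
    fused <- naive_conv(x, acb_fused_kernel(blk), ph = 1, pw = 1)
    expect_lt(max(abs(blk$branch_sum(x) - fused)), 1e-5)
  }
  set.seed(1)
  blk <- acb_block(1L, 2L)
  y <- block_forward(blk, array(rnorm(10 * 10), c(10, 10, 1, 1)), training = TRUE)
  expect_equal(dim(y), c(10, 10, 2, 1))
})

test_that("channel attention squeezes by 1/16 and emits weights in (0,1)", {
  expect_error(chab_block(16L, 24L), "divisible")
  set.seed(12)
  blk <- chab_block(8L, 16L, ratio = 16L)
  expect_equal(dim(blk$children$reduce$params$w$v), c(1, 1, 8, 16))
  expect_equal(dim(blk$children$squeeze$params$w$v), c(1, 16))
  x <- array(rnorm(6 * 6 * 8 * 3), c(6, 6, 8, 3))
  y <- block_forward(blk, x)
  expect_equal(dim(y), c(6, 6, 16, 3))
  w <- blk$last_weights
  expect_true(all(w > 0 & w < 1))
  # saturation: huge positive restore biases push the weights to ~1
  blk$children$restore$params$b$v[] <- 50
  y2 <- block_forward(blk, x)
  f <- blk$children$reduce$fw(noduleseg:::ag_const(x))$v
  expect_equal(y2, f, tolerance = 1e-6)
  # constant-over-space input: both pooling paths coincide
  const <- array(rep(rnorm(8 * 2), each = 25), c(5, 5, 8, 2))
  blk2 <- chab_block(8L, 16L)
  f2 <- blk2$children$reduce$fw(noduleseg:::ag_const(const))
  gap <- noduleseg:::op_gap(f2)$v
  gmp <- noduleseg:::op_gmp(f2)$v
  expect_equal(gap, gmp, tolerance = 1e-9)
})

test_that("blocks propagate gradients to every parameter", {
  set.seed(13)
  ns <- asNamespace("noduleseg")
  specs <- list(list(blk = multiscale_block(2L, 4L), cin = 2L),
                list(blk = acb_block(2L, 4L), cin = 2L),
                list(blk = chab_block(4L, 16L), cin = 4L))
  for (sp in specs) {
    blk <- sp$blk
    x <- array(rnorm(8 * 8 * sp$cin * 2), c(8, 8, sp$cin, 2))
    out <- blk$fw(ns$ag_const(x), training = TRUE)
    loss <- ns$ag_tensor(sum(out$v^2), list(out),
                         bw = function(g) list(2 * g * out$v))
    ns$ag_backward(loss)
    for (p in ns$collect_params(blk)) {
      expect_false(is.null(p$grad))
      expect_true(any(p$grad != 0))
    }
  }
})
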