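test_that("QKV projection is plain matrix multiplication", {
  set.seed(21)
  I <- matrix(rnorm(6), 3, 2)
  wq <- matrix(c(1, 0, 0, 1), 2, 2)
  qkv <- project_qkv(I, wq, wq, wq)
  expect_equal(qkv$Q, I)
  expect_equal(qkv$K, I)
  expect_equal(qkv$V, I)
  zero_v <- project_qkv(I, wq, wq, matrix(0, 2, 3))
  expect_true(all(zero_v$V == 0))
  # printed-in-test weights against a naive triple loop
  wq2 <- matrix(c(0.5, -1, 2, 0.25), 2, 2)
  wv2 <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  qkv2 <- project_qkv(I, wq2, wq2, wv2)
  ref <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) for (k in 1:2) ref[i, j] <- ref[i, j] + I[i, k] * wv2[k, j]
  expect_equal(qkv2$V, ref)
  expect_error(project_qkv(I, wq, matrix(0, 2, 3), wq), "same number of columns")
  expect_error(project_qkv(I, matrix(0, 3, 2), wq, wq), "as many rows")
})

test_that("softmax attention is a proper convex combination of values", {
  set.seed(22)
  Q <- matrix(rnorm(8), 4, 2); K <- matrix(rnorm(8), 4, 2); V <- matrix(rnorm(12), 4, 3)
  out <- softmax_attention(Q, K, V)
  S <- exp(Q %*% t(K) - apply(Q %*% t(K), 1, max))
  W <- S / rowSums(S)
  expect_equal(rowSums(W), rep(1, 4), tolerance = 1e-9)
  expect_true(all(W >= 0))
  expect_equal(out, W %*% V)
  # single position: the value row comes back unchanged
  expect_equal(softmax_attention(Q[1, , drop = FALSE], K[1, , drop = FALSE],
                                 V[1, , drop = FALSE]), V[1, , drop = FALSE])
  # identical keys: uniform weights, every row is the value mean
  Kc <- matrix(1, 4, 2)
  outc <- softmax_attention(Q, Kc, V)
  expect_equal(outc, matrix(colMeans(V), 4, 3, byrow = TRUE), tolerance = 1e-12)
})

test_that("linear attention matches the double-sum oracle with unit weights", {
  for (s in 1:20) {
    set.seed(s)
    M <- sample(2:64, 1); Dk <- sample(1:16, 1); Dv <- sample(1:16, 1)
    Q <- matrix(rnorm(M * Dk), M); K <- matrix(rnorm(M * Dk), M); V <- matrix(rnorm(M * Dv), M)
    expect_lt(max(abs(linear_attention(Q, K, V) - double_sum_attention(Q, K, V))), 1e-6)
    # implicit weights are non-negative and sum to one
    eps <- 1e-6
    Qh <- Q / (sqrt(rowSums(Q^2)) + eps); Kh <- K / (sqrt(rowSums(K^2)) + eps)
    for (x in c(1L, M)) {
      wts <- (1 + as.vector(Kh %*% Qh[x, ])) / (M + sum(Qh[x, ] * colSums(Kh)))
      expect_true(all(wts >= -1e-12))
      expect_equal(sum(wts), 1, tolerance = 1e-6)
    }
  }
  # M = 1 cancellation
  q <- matrix(c(1, 2), 1); k <- matrix(c(-3, 1), 1); v <- matrix(c(5, -2, 7), 1)
  expect_equal(linear_attention(q, k, v), v, tolerance = 1e-6)
  expect_error(linear_attention(matrix(0, 2, 2), q[c(1, 1), ], v[c(1, 1), ]), "zero-norm")
})

test_that("attention outputs converge to the value mean as scores are scaled down", {
  # shrinking Q and K drives softmax scores to zero directly, and drives the
  # normalized queries/keys of the linear form to zero through the eps guard
  # on the L2 norms, so both attentions flatten to uniform weights
  set.seed(23)
  M <- 24
  Q <- matrix(rnorm(M * 4), M); K <- matrix(rnorm(M * 4), M); V <- matrix(rnorm(M * 3), M)
  vm <- matrix(colMeans(V), M, 3, byrow = TRUE)
  prev <- Inf
  for (s in c(1e-6, 1e-7, 1e-8, 1e-9)) {
    so <- softmax_attention(s * Q, s * K, V)
    li <- linear_attention(s * Q, s * K, V)
    d <- max(abs(so - li))
    expect_lte(d, prev + 1e-12)
    prev <- d
  }
  expect_lt(max(abs(softmax_attention(1e-10 * Q, 1e-10 * K, V) - vm)), 1e-6)
  expect_lt(max(abs(linear_attention(1e-10 * Q, 1e-10 * K, V) - vm)), 1e-3)
})

test_that("permutation equivariance holds for queries and joint key/value rows", {
  set.seed(24)
  M <- 10
  Q <- matrix(rnorm(M * 3), M); K <- matrix(rnorm(M * 3), M); V <- matrix(rnorm(M * 2), M)
  perm <- sample(M)
  base <- linear_attention(Q, K, V)
  expect_equal(linear_attention(Q[perm, ], K, V), base[perm, ], tolerance = 1e-12)
  expect_equal(linear_attention(Q, K[perm, ], V[perm, ]), base, tolerance = 1e-12)
})

test_that("attention aggregation fuses the pyramid with a residual path", {
  set.seed(25)
  ns <- asNamespace("noduleseg")
  d <- 8L
  agg <- attention_aggregation(d)
  ps <- lapply(c(8L, 4L, 2L, 1L), function(sz) {
    ns$ag_const(array(rnorm(sz * sz * d * 2), c(sz, sz, d, 2)))
  })
  out <- agg$fw(ps)
  expect_equal(dim(out$v), c(8, 8, 4 * d, 2))
  # zero value projection: pure residual, output equals the concatenation
  agg$children$wv$params$w$v[] <- 0
  out2 <- agg$fw(ps)
  cat4 <- ns$op_concat_c(c(ps[1], lapply(2:4, function(i) {
    ns$op_upsample(ps[[i]], 2L^(i - 1L), "nearest")
  })))
  expect_equal(out2$v, cat4$v, tolerance = 1e-12)
  expect_error(agg$fw(list(ps[[1]], ps[[2]], ps[[3]],
                           ns$ag_const(array(0, c(1, 1, d, 3))))), "batch|dim")
})
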