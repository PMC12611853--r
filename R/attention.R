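# Dot-product attention (quadratic reference) and its linear-time
# approximation: softmax replaced by a first-order Taylor expansion over
# L2-normalized queries and keys, so the key/value summaries are computed
# once and reused for every query.

#' Project an input into query, key and value matrices
#'
#' Computes `Q = I W_q`, `K = I W_k`, `V = I W_v` for an input of flattened
#' spatial features `I` (one row per spatial position).
#'
#' @param input `M x D_i` numeric matrix of flattened features.
#' @param w_q,w_k `D_i x D_k` projection matrices (query and key widths must
#'   match).
#' @param w_v `D_i x D_v` value projection matrix.
#' @return list with matrices `Q` (`M x D_k`), `K` (`M x D_k`), `V` (`M x D_v`).
#' @export
project_qkv <- function(input, w_q, w_k, w_v) {
  input <- as.matrix(input)
  if (ncol(input) != nrow(w_q) || ncol(input) != nrow(w_k) || ncol(input) != nrow(w_v)) {
    stop("projection matrices must have as many rows as the input has columns")
  }
  if (ncol(w_q) != ncol(w_k)) {
    stop("query and key projections must have the same number of columns")
  }
  list(Q = input %*% w_q, K = input %*% w_k, V = input %*% w_v)
}

#' Softmax dot-product attention (quadratic reference)
#'
#' Row `x` of the output is `sum_y softmax_y(q_x . k_y) v_y`. This is the
#' O(M^2) reference implementation used as the oracle for the linear
#' variant; scores are max-shifted per row for overflow safety.
#'
#' @param Q,K `M x D_k` query and key matrices.
#' @param V `M x D_v` value matrix.
#' @return `M x D_v` matrix of attended values.
#' @export
softmax_attention <- function(Q, K, V) {
  stopifnot(nrow(Q) == nrow(K), nrow(K) == nrow(V), ncol(Q) == ncol(K))
  S <- Q %*% t(K)
  S <- exp(S - apply(S, 1L, max))
  W <- S / rowSums(S)
  W %*% V
}

lin_att_core <- function(Q, K, V, eps = 1e-6) {
  nq <- sqrt(rowSums(Q^2))
  nk <- sqrt(rowSums(K^2))
  if (any(nq == 0)) stop("zero-norm query row(s): ", paste(which(nq == 0), collapse = ", "))
  if (any(nk == 0)) stop("zero-norm key row(s): ", paste(which(nk == 0), collapse = ", "))
  Qh <- Q / (nq + eps)
  Kh <- K / (nk + eps)
  M <- nrow(Q)
  S <- crossprod(Kh, V)        # sum_y khat_y v_y^T  (D_k x D_v)
  z <- colSums(Kh)             # sum_y khat_y       (D_k)
  vs <- colSums(V)             # sum_y v_y          (D_v)
  num <- sweep(Qh %*% S, 2L, vs, "+")
  den <- as.vector(M + Qh %*% z)
  if (any(den <= eps)) stop("attention denominator vanished (all keys antipodal to a query)")
  list(out = num / den, Qh = Qh, Kh = Kh, S = S, z = z, vs = vs,
       den = den, nq = nq, nk = nk, eps = eps)
}

#' Linear attention (first-order Taylor approximation)
#'
#' Approximates softmax attention by `exp(q.k) ~ 1 + q.k` on L2-normalized
#' queries and keys (the normalization guarantees `q.k >= -1`, so the
#' implicit weights stay non-negative). Row `x` of the output is
#' \deqn{\left[\sum_y v_y + \hat q_x^\top \sum_y \hat k_y v_y^\top\right] /
#'       \left[M + \hat q_x^\top \sum_y \hat k_y\right].}
#' The two key summaries are computed once and reused for every query, so
#' the cost is O(M) in the number of spatial positions and no `M x M` array
#' is ever formed.
#'
#' @inheritParams softmax_attention
#' @param eps stabilizer added to the L2 norms; a denominator at or below
#'   it (all keys antipodal to a query) raises an error.
#' @return `M x D_v` matrix of attended values.
#' @export
linear_attention <- function(Q, K, V, eps = 1e-6) {
  stopifnot(nrow(Q) == nrow(K), nrow(K) == nrow(V), ncol(Q) == ncol(K))
  lin_att_core(Q, K, V, eps)$out
}

# Autodiff linear attention on (M, D, N) arrays (batched over N).
op_linear_attention <- function(Q, K, V, eps = 1e-6) {
  dq <- dim(Q$v); dv <- dim(V$v)
  N <- dq[3L]
  dk <- dim(K$v)
  y <- array(0, c(dq[1L], dv[2L], N))
  cache <- vector("list", N)
  slice <- function(a, d, n) matrix(a[, , n], d[1L], d[2L])
  for (n in seq_len(N)) {
    cc <- lin_att_core(slice(Q$v, dq, n), slice(K$v, dk, n), slice(V$v, dv, n), eps)
    y[, , n] <- cc$out
    cache[[n]] <- cc
  }
  ag_tensor(y, list(Q, K, V), bw = function(g) {
    dim(g) <- dim(y)
    gQ <- array(0, dq); gK <- array(0, dk); gV <- array(0, dv)
    for (n in seq_len(N)) {
      cc <- cache[[n]]
      G <- matrix(g[, , n], dq[1L], dv[2L])
      Gd <- G / cc$den                       # dL/d numerator
      gden <- -rowSums(G * cc$out) / cc$den  # dL/d denominator (scalar per row)
      # numerator = 1 vs^T + Qh S ; denominator = M + Qh z
      gQh <- Gd %*% t(cc$S) + outer(gden, cc$z)
      gS <- crossprod(cc$Qh, Gd)
      gz <- as.vector(crossprod(cc$Qh, gden))
      gvs <- colSums(Gd)
      Vn <- slice(V$v, dv, n)
      gKh <- Vn %*% t(gS) + matrix(gz, nrow = dq[1L], ncol = length(gz), byrow = TRUE)
      gVn <- cc$Kh %*% gS + matrix(gvs, nrow = dq[1L], ncol = length(gvs), byrow = TRUE)
      # back through q / (|q| + eps)
      qv <- slice(Q$v, dq, n); kv <- slice(K$v, dk, n)
      s1 <- rowSums(qv * gQh)
      gQ[, , n] <- gQh / (cc$nq + cc$eps) - qv * (s1 / (cc$nq * (cc$nq + cc$eps)^2))
      s2 <- rowSums(kv * gKh)
      gK[, , n] <- gKh / (cc$nk + cc$eps) - kv * (s2 / (cc$nk * (cc$nk + cc$eps)^2))
      gV[, , n] <- gVn
    }
    list(if (Q$req) gQ else NULL, if (K$req) gK else NULL, if (V$req) gV else NULL)
  })
}

#' Attention aggregation over pyramid features
#'
#' Builds the module that fuses the four pyramid maps P2..P5: P3..P5 are
#' upsampled (nearest neighbour) to P2's resolution, the four maps are
#' concatenated (4 d channels), fused by a 1x1 convolution, refined by
#' single-head linear attention over the flattened spatial positions (QKV
#' from 1x1 convolutions, embedding = concatenated width), and the refined
#' map is added residually to the concatenated features.
#'
#' @param d channel width of each pyramid map (concatenated width is `4 d`).
#' @return a network module whose `fw` takes a list `list(p2, p3, p4, p5)`
#'   of tensors.
#' @export
attention_aggregation <- function(d = 64L) {
  ch <- 4L * d
  m <- new_module("att_agg")
  mod_child(m, "fuse", layer_conv(1L, 1L, ch, ch))
  mod_child(m, "wq", layer_conv(1L, 1L, ch, ch, bias = FALSE))
  mod_child(m, "wk", layer_conv(1L, 1L, ch, ch, bias = FALSE))
  mod_child(m, "wv", layer_conv(1L, 1L, ch, ch, bias = FALSE))
  m$fw <- function(ps, training = FALSE) {
    p2 <- ps[[1L]]
    up <- lapply(2:4, function(i) op_upsample(ps[[i]], 2L^(i - 1L), "nearest"))
    cat4 <- op_concat_c(c(list(p2), up))
    fused <- m$children$fuse$fw(cat4, training)
    q <- m$children$wq$fw(fused, training)
    k <- m$children$wk$fw(fused, training)
    v <- m$children$wv$fw(fused, training)
    dd <- dim(fused$v)
    mrows <- dd[1L] * dd[2L]
    to_mat <- function(t) op_reshape(t, c(mrows, dd[3L], dd[4L]))
    refined <- op_linear_attention(to_mat(q), to_mat(k), to_mat(v))
    op_add(cat4, op_reshape(refined, dd))
  }
  m
}
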