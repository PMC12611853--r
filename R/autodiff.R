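# Reverse-mode automatic differentiation on dense arrays.
#
# A tensor is an environment holding a value (`v`), an accumulated gradient
# (`grad`), its `parents` and a backward closure `bw(g)` returning one
# gradient per parent (NULL where a parent needs no gradient). Rank-4
# feature maps use the (H, W, C, N) column-major layout throughout.

.ag_counter <- new.env(parent = emptyenv())
.ag_counter$n <- 0L

ag_tensor <- function(v, parents = list(), bw = NULL, req = NULL) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  e$parents <- parents
  e$bw <- bw
  e$req <- if (is.null(req)) {
    any(vapply(parents, function(p) p$req, logical(1)))
  } else req
  .ag_counter$n <- .ag_counter$n + 1L
  e$id <- .ag_counter$n
  class(e) <- "ag_tensor"
  e
}

ag_param <- function(v) ag_tensor(v, req = TRUE)
ag_const <- function(v) ag_tensor(v, req = FALSE)

ag_is <- function(x) inherits(x, "ag_tensor")

#' @export
print.ag_tensor <- function(x, ...) {
  d <- dim(x$v)
  cat("<tensor", if (is.null(d)) length(x$v) else paste(d, collapse = "x"),
      if (x$req) "grad" else "const", ">\n")
  invisible(x)
}

# Topologically ordered reverse sweep from a scalar (or any) root.
ag_backward <- function(root, seed_grad = NULL) {
  topo <- vector("list", 256L)
  ntopo <- 0L
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  visit <- function(node) {
    key <- as.character(node$id)
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    if (node$req) for (p in node$parents) visit(p)
    ntopo <<- ntopo + 1L
    if (ntopo > length(topo)) length(topo) <<- 2L * ntopo
    topo[[ntopo]] <<- node
    invisible(NULL)
  }
  visit(root)
  root$grad <- if (is.null(seed_grad)) {
    g <- root$v
    g[] <- 1
    g
  } else seed_grad
  for (i in seq(ntopo, 1L)) {
    node <- topo[[i]]
    if (is.null(node$bw) || !node$req || is.null(node$grad)) next
    gs <- node$bw(node$grad)
    ps <- node$parents
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      g <- gs[[k]]
      if (!p$req || is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    if (length(ps)) node$grad <- NULL  # free intermediate gradients
  }
  invisible(root)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- shape helpers -------------------------------------------------------

# per-channel sum of a (H,W,C,N) array -> length-C vector
csum4 <- function(g) {
  d <- dim(g)
  s <- .colSums(g, d[1L] * d[2L], d[3L] * d[4L])
  .rowSums(matrix(s, nrow = d[3L]), d[3L], d[4L])
}

# broadcast a length-C vector over a (H,W,C,N) array shape -> plain vector
bcast_c <- function(vec, d) {
  rep(rep(vec, each = d[1L] * d[2L]), times = d[4L])
}

# per-(C,N) sum -> C x N matrix
csum_cn <- function(g) {
  d <- dim(g)
  matrix(.colSums(g, d[1L] * d[2L], d[3L] * d[4L]), nrow = d[3L])
}

# broadcast a C x N matrix over (H,W,C,N)
bcast_cn <- function(m, d) rep(as.vector(m), each = d[1L] * d[2L])

# ---- core ops ------------------------------------------------------------

op_conv2d <- function(x, w, stride = 1L, ph = 0L, pw = 0L, b = NULL) {
  y <- cpp_conv_fwd(x$v, w$v, stride, ph, pw)
  if (!is.null(b)) y <- cpp_chan_affine(y, rep(1, length(b$v)), b$v)
  dx <- dim(x$v)
  dw <- dim(w$v)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_tensor(y, parents, bw = function(g) {
    dim(g) <- dim(y)
    gx <- if (x$req) cpp_conv_bwd_data(g, w$v, stride, ph, pw, dx[1L], dx[2L]) else NULL
    gw <- if (w$req) cpp_conv_bwd_w(x$v, g, stride, ph, pw, dw[1L], dw[2L]) else NULL
    if (is.null(b)) list(gx, gw) else list(gx, gw, csum4(g))
  })
}

# Transposed convolution, kernel 2x2, stride 2 (exact 2x upsampling).
# Weight layout is conv-oriented: (2, 2, c_out, c_in).
op_convT2 <- function(x, w, b = NULL) {
  dx <- dim(x$v)
  y <- cpp_conv_bwd_data(x$v, w$v, 2L, 0L, 0L, dx[1L] * 2L, dx[2L] * 2L)
  if (!is.null(b)) y <- cpp_chan_affine(y, rep(1, length(b$v)), b$v)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_tensor(y, parents, bw = function(g) {
    dim(g) <- dim(y)
    gx <- if (x$req) cpp_conv_fwd(g, w$v, 2L, 0L, 0L) else NULL
    gw <- if (w$req) cpp_conv_bwd_w(g, x$v, 2L, 0L, 0L, 2L, 2L) else NULL
    if (is.null(b)) list(gx, gw) else list(gx, gw, csum4(g))
  })
}

op_maxpool2 <- function(x) {
  r <- cpp_maxpool2(x$v)
  len <- length(x$v)
  dx <- dim(x$v)
  ag_tensor(r$y, list(x), bw = function(g) {
    gx <- numeric(len)
    gx[r$idx] <- as.vector(g)
    dim(gx) <- dx
    list(gx)
  })
}

op_upsample <- function(x, f, mode = c("nearest", "bilinear")) {
  mode <- match.arg(mode)
  y <- if (mode == "nearest") cpp_upsample_nearest(x$v, f) else cpp_upsample_bilinear(x$v, f)
  ag_tensor(y, list(x), bw = function(g) {
    dim(g) <- dim(y)
    list(if (mode == "nearest") cpp_upsample_nearest_bwd(g, f) else cpp_upsample_bilinear_bwd(g, f))
  })
}

op_add <- function(a, b) {
  ag_tensor(a$v + b$v, list(a, b), bw = function(g) list(g, g))
}

op_concat_c <- function(xs) {
  d1 <- dim(xs[[1L]]$v)
  for (x in xs) {
    if (!identical(dim(x$v)[c(1L, 2L, 4L)], d1[c(1L, 2L, 4L)])) {
      stop("concat: feature maps differ in spatial or batch dims")
    }
  }
  chs <- vapply(xs, function(x) dim(x$v)[3L], numeric(1))
  Cout <- sum(chs)
  y <- array(0, c(d1[1L], d1[2L], Cout, d1[4L]))
  at <- 0L
  for (x in xs) {
    dc <- dim(x$v)[3L]
    y[, , at + seq_len(dc), ] <- x$v
    at <- at + dc
  }
  ag_tensor(y, xs, bw = function(g) {
    dim(g) <- dim(y)
    out <- vector("list", length(xs))
    at <- 0L
    for (k in seq_along(xs)) {
      dc <- chs[k]
      out[[k]] <- g[, , at + seq_len(dc), , drop = FALSE]
      at <- at + dc
    }
    out
  })
}

op_reshape <- function(x, newdim) {
  olddim <- dim(x$v)
  y <- x$v
  dim(y) <- newdim
  ag_tensor(y, list(x), bw = function(g) {
    dim(g) <- olddim
    list(g)
  })
}

# multiply each channel of x (H,W,C,N) by a weight from w (C x N)
op_scale_channels <- function(x, w) {
  dx <- dim(x$v)
  wv <- bcast_cn(w$v, dx)
  y <- x$v * wv
  dim(y) <- dx
  ag_tensor(y, list(x, w), bw = function(g) {
    gx <- if (x$req) {
      gg <- g * wv
      dim(gg) <- dx
      gg
    } else NULL
    gw <- if (w$req) csum_cn(g * x$v) else NULL
    list(gx, gw)
  })
}

op_gap <- function(x) {
  d <- dim(x$v)
  hw <- d[1L] * d[2L]
  y <- matrix(.colSums(x$v, hw, d[3L] * d[4L]) / hw, nrow = d[3L])
  ag_tensor(y, list(x), bw = function(g) {
    gx <- bcast_cn(g / hw, d)
    dim(gx) <- d
    list(gx)
  })
}

op_gmp <- function(x) {
  d <- dim(x$v)
  hw <- d[1L] * d[2L]
  m <- matrix(x$v, nrow = hw)
  jj <- seq_len(ncol(m))
  ii <- max.col(t(m), ties.method = "first")
  y <- matrix(m[cbind(ii, jj)], nrow = d[3L])
  lin <- ii + (jj - 1L) * hw
  ag_tensor(y, list(x), bw = function(g) {
    gx <- numeric(length(x$v))
    gx[lin] <- as.vector(g)
    dim(gx) <- d
    list(gx)
  })
}

# dense layer on (in x N) column-sample matrices
op_dense <- function(w, x, b = NULL) {
  y <- w$v %*% x$v
  if (!is.null(b)) y <- y + b$v
  parents <- if (is.null(b)) list(w, x) else list(w, x, b)
  ag_tensor(y, parents, bw = function(g) {
    gw <- if (w$req) g %*% t(x$v) else NULL
    gx <- if (x$req) crossprod(w$v, g) else NULL
    if (is.null(b)) list(gw, gx) else list(gw, gx, rowSums(g))
  })
}

# probability outputs are clipped into the open unit interval so that
# downstream log-likelihoods stay finite even for saturated logits
op_sigmoid <- function(x) {
  y <- pmin(pmax(stats::plogis(x$v), 1e-7), 1 - 1e-7)
  dim(y) <- dim(x$v)
  ag_tensor(y, list(x), bw = function(g) list(g * y * (1 - y)))
}

op_act <- function(x, act) {
  if (isTRUE(act$name == "GELU") && !isTRUE(act$params$tanh_approx)) {
    r <- cpp_gelu_both(x$v)
    ag_tensor(r$y, list(x), bw = function(g) list(g * r$d))
  } else {
    y <- act$f(x$v)
    ag_tensor(y, list(x), bw = function(g) list(g * act$df(x$v)))
  }
}

# Fused forward of the three ACB branches: the 3x3 + 1x3 + 3x1 branch sum
# equals one convolution with the fused 3x3 kernel, and the branch-kernel
# gradients are slices of the fused-kernel gradient.
op_conv_acb <- function(x, k33, k13, k31) {
  wf <- k33$v
  wf[2L, , , ] <- wf[2L, , , , drop = FALSE] + k13$v
  wf[, 2L, , ] <- wf[, 2L, , , drop = FALSE] + k31$v
  y <- cpp_conv_fwd(x$v, wf, 1L, 1L, 1L)
  dx <- dim(x$v)
  ag_tensor(y, list(x, k33, k13, k31), bw = function(g) {
    dim(g) <- dim(y)
    gx <- if (x$req) cpp_conv_bwd_data(g, wf, 1L, 1L, 1L, dx[1L], dx[2L]) else NULL
    gwf <- cpp_conv_bwd_w(x$v, g, 1L, 1L, 1L, 3L, 3L)
    list(gx, gwf,
         gwf[2L, , , , drop = FALSE],
         gwf[, 2L, , , drop = FALSE])
  })
}

# ---- batch normalization -------------------------------------------------

# `bn` is a layer environment with running_mean / running_var buffers.
op_batchnorm <- function(x, gamma, beta, bn, training) {
  d <- dim(x$v)
  m <- d[1L] * d[2L] * d[4L]
  if (training) {
    mv <- cpp_chan_mean_var(x$v)
    mu <- mv$mean
    va <- mv$var
    bn$running_mean <- (1 - bn$momentum) * bn$running_mean + bn$momentum * mu
    bn$running_var <- (1 - bn$momentum) * bn$running_var + bn$momentum * va * m / max(m - 1, 1)
  } else {
    mu <- bn$running_mean
    va <- bn$running_var
  }
  inv <- 1 / sqrt(va + bn$eps)
  xhat <- cpp_chan_affine(x$v, inv, -mu * inv)
  y <- cpp_chan_affine(xhat, gamma$v, beta$v)
  ag_tensor(y, list(x, gamma, beta), bw = function(g) {
    dim(g) <- d
    if (training) {
      r <- cpp_bn_bwd(g, xhat, gamma$v, inv)
      list(if (x$req) r$gx else NULL,
           if (gamma$req) r$ggamma else NULL,
           if (beta$req) r$gbeta else NULL)
    } else {
      ggamma <- if (gamma$req) csum4(g * xhat) else NULL
      gbeta <- if (beta$req) csum4(g) else NULL
      gx <- if (x$req) cpp_chan_affine(g, gamma$v * inv, numeric(d[3L])) else NULL
      list(gx, ggamma, gbeta)
    }
  })
}

# ---- losses --------------------------------------------------------------

# Combined binary cross-entropy + Dice loss on probability maps.
op_bce_dice <- function(pred, target, w_bce = 0.5, w_dice = 0.5, smooth = 1.0) {
  p <- pmin(pmax(pred$v, 1e-7), 1 - 1e-7)
  t <- target
  n <- length(p)
  bce <- -mean(t * log(p) + (1 - t) * log(1 - p))
  A <- 2 * sum(p * t) + smooth
  B <- sum(p) + sum(t) + smooth
  dice <- 1 - A / B
  val <- w_bce * bce + w_dice * dice
  ag_tensor(val, list(pred), bw = function(g) {
    gb <- (-t / p + (1 - t) / (1 - p)) / n
    gd <- -(2 * t * B - A) / (B * B)
    gp <- as.numeric(g) * (w_bce * gb + w_dice * gd)
    dim(gp) <- dim(pred$v)
    list(gp)
  })
}
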