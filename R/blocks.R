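# Network building blocks: multi-scale convolution block, asymmetric
# convolution block (ACB) and channel attention block (ChAB).

#' Multi-scale convolution block
#'
#' Two parallel same-padded convolution paths with 3x3 and 7x7 kernels (each
#' batch-normalized and activated) capture fine detail and wider context;
#' their outputs are concatenated and fused by a 1x1 convolution down to
#' `cout` channels. Spatial size is preserved.
#'
#' @param cin,cout input / output channel counts.
#' @param act an [activation()] object.
#' @return a network module; apply it with [block_forward()].
#' @export
multiscale_block <- function(cin, cout, act = activation("GELU")) {
  m <- new_module("multiscale")
  mod_child(m, "path3", layer_cba(3L, 3L, cin, cout, act))
  mod_child(m, "path7", layer_cba(7L, 7L, cin, cout, act))
  mod_child(m, "fuse", layer_conv(1L, 1L, 2L * cout, cout))
  m$fw <- function(x, training = FALSE) {
    a <- m$children$path3$fw(x, training)
    b <- m$children$path7$fw(x, training)
    m$children$fuse$fw(op_concat_c(list(a, b)), training)
  }
  m
}

#' Asymmetric convolution block (ACB)
#'
#' Sums the outputs of parallel 3x3, 1x3 and 3x1 convolutions (emphasizing
#' the central cross of the receptive field), then applies batch
#' normalization and a nonlinearity. All branches are same-padded so the
#' spatial size is preserved.
#'
#' @inheritParams multiscale_block
#' @return a network module. The module also exposes `branch_sum(x)`, the
#'   pre-normalization sum of the three branches, used by the fused-kernel
#'   equivalence check.
#' @seealso [acb_fused_kernel()]
#' @export
acb_block <- function(cin, cout, act = activation("GELU")) {
  m <- new_module("acb")
  mod_child(m, "k33", layer_conv(3L, 3L, cin, cout, bias = FALSE))
  mod_child(m, "k13", layer_conv(1L, 3L, cin, cout, bias = FALSE))
  mod_child(m, "k31", layer_conv(3L, 1L, cin, cout, bias = FALSE))
  mod_child(m, "bn", layer_bn(cout))
  m$branches <- function(x, training = FALSE) {
    op_add(op_add(m$children$k33$fw(x, training),
                  m$children$k13$fw(x, training)),
           m$children$k31$fw(x, training))
  }
  m$branch_sum <- function(x) {
    if (!ag_is(x)) x <- ag_const(x)
    m$branches(x)$v
  }
  m$fw <- function(x, training = FALSE) {
    h <- op_conv_acb(x, m$children$k33$params$w, m$children$k13$params$w,
                     m$children$k31$params$w)
    op_act(m$children$bn$fw(h, training), act)
  }
  m
}

#' Fused equivalent kernel of an ACB
#'
#' The three parallel branches of an ACB are linear, so their sum equals a
#' single 3x3 convolution whose kernel is the 3x3 kernel plus the 1x3 kernel
#' zero-padded into the middle row plus the 3x1 kernel zero-padded into the
#' middle column.
#'
#' @param block an [acb_block()].
#' @return the fused kernel, a (3, 3, cin, cout) array.
#' @export
acb_fused_kernel <- function(block) {
  k <- block$children$k33$params$w$v
  k13 <- block$children$k13$params$w$v  # (1,3,cin,cout)
  k31 <- block$children$k31$params$w$v  # (3,1,cin,cout)
  k[2L, , , ] <- k[2L, , , , drop = FALSE] + k13
  k[, 2L, , ] <- k[, 2L, , , drop = FALSE] + k31
  k
}

#' Channel attention block (ChAB)
#'
#' Reduces the input with a 1x1 convolution to `reduce` channels, squeezes
#' the spatial dimension by global average and global max pooling, passes
#' each pooled vector through a two-layer bottleneck (squeeze to
#' `reduce / ratio` channels, restore to `reduce`; the bottleneck weights
#' are shared between the two pooling branches, as in CBAM), sums the two
#' restored vectors and applies a sigmoid to obtain per-channel weights in
#' (0,1) that rescale the reduced map.
#'
#' @param cin input channels.
#' @param reduce channels after the initial 1x1 convolution (also the output
#'   width).
#' @param ratio squeeze ratio; `reduce` must be divisible by it.
#' @param act activation used inside the squeeze bottleneck.
#' @return a network module exposing `last_weights` (the most recent
#'   attention weights, a `reduce x N` matrix) after a forward pass.
#' @export
chab_block <- function(cin, reduce, ratio = 16L, act = activation("GELU")) {
  if (reduce %% ratio != 0) {
    stop("ChAB reduce channels (", reduce, ") must be divisible by the squeeze ratio (", ratio, ")")
  }
  sq <- reduce %/% ratio
  m <- new_module("chab")
  mod_child(m, "reduce", layer_conv(1L, 1L, cin, reduce))
  mod_child(m, "squeeze", layer_dense(reduce, sq))
  mod_child(m, "restore", layer_dense(sq, reduce))
  m$fw <- function(x, training = FALSE) {
    f <- m$children$reduce$fw(x, training)
    mlp <- function(p) m$children$restore$fw(op_act(m$children$squeeze$fw(p), act))
    w <- op_sigmoid(op_add(mlp(op_gap(f)), mlp(op_gmp(f))))
    m$last_weights <- w$v
    op_scale_channels(f, w)
  }
  m
}

#' Run a network block on a plain array
#'
#' Convenience wrapper applying a block built by [multiscale_block()],
#' [acb_block()] or [chab_block()] to a numeric `(H, W, C, N)` array,
#' returning the output array.
#'
#' @param block a network module.
#' @param x a rank-4 numeric array, layout `(height, width, channels, batch)`.
#' @param training logical; use batch statistics in normalization layers.
#' @return the output feature map as a rank-4 array.
#' @export
block_forward <- function(block, x, training = FALSE) {
  if (length(dim(x)) != 4L) stop("block input must be a rank-4 (H, W, C, N) array")
  block$fw(ag_const(x), training = training)$v
}
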