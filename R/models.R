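# Segmentation architectures: multi-scale UNet, UNet with ACBs,
# multi-scale skip connections and channel attention, and a ResNet-34
# feature pyramid network with linear-attention aggregation.

#' Model configuration
#'
#' @param architecture `"msunet"` (multi-scale UNet), `"acb_unet"` (UNet with
#'   asymmetric convolution blocks, multi-scale skip connections and channel
#'   attention) or `"fpn_la"` (ResNet-34 feature pyramid network with
#'   linear-attention aggregation).
#' @param in_channels input image channels (1 for grayscale CT).
#' @param activation an [activation()] object (GELU by default).
#' @param pyramid_width channel width `d` of each pyramid map in `fpn_la`;
#'   the four concatenated maps then carry `4 d` channels (256 by default).
#' @param widths encoder widths per level. Defaults:
#'   `c(32, 64, 128, 256)` plus a 512-channel bottleneck for `msunet`, and
#'   `c(32, 64, 128, 256, 512)` (5 levels) for `acb_unet`.
#' @param seed integer seed for weight initialization.
#' @return a `nodseg_model_config` list.
#' @export
model_config <- function(architecture = c("fpn_la", "msunet", "acb_unet"),
                         in_channels = 1L,
                         activation = NULL,
                         pyramid_width = 64L,
                         widths = NULL,
                         seed = 1L) {
  architecture <- match.arg(architecture)
  if (is.null(activation)) activation <- noduleseg::activation("GELU")
  if (is.null(widths)) {
    widths <- switch(architecture,
      msunet = c(16L, 32L, 64L, 128L),
      acb_unet = c(32L, 64L, 128L, 256L, 512L),
      fpn_la = c(64L, 128L, 256L, 512L))
  }
  structure(list(architecture = architecture, in_channels = in_channels,
                 activation = activation, pyramid_width = pyramid_width,
                 widths = widths, seed = seed),
            class = "nodseg_model_config")
}

# ---- multi-scale UNet ----------------------------------------------------

build_msunet <- function(cfg) {
  act <- cfg$activation
  w <- cfg$widths
  bott <- 2L * w[length(w)]
  m <- new_module("msunet")
  cin <- cfg$in_channels
  for (j in seq_along(w)) {
    mod_child(m, paste0("enc", j), multiscale_block(cin, w[j], act))
    cin <- w[j]
  }
  mod_child(m, "bottleneck", multiscale_block(w[length(w)], bott, act))
  up_in <- bott
  for (j in rev(seq_along(w))) {
    mod_child(m, paste0("up", j), layer_convT2(up_in, w[j]))
    mod_child(m, paste0("dec", j), multiscale_block(2L * w[j], w[j], act))
    up_in <- w[j]
  }
  mod_child(m, "head", layer_conv(1L, 1L, w[1L], 1L))
  m$depth <- length(w)
  m$fw <- function(x, training = FALSE) {
    skips <- vector("list", m$depth)
    h <- x
    for (j in seq_len(m$depth)) {
      h <- m$children[[paste0("enc", j)]]$fw(h, training)
      skips[[j]] <- h
      h <- op_maxpool2(h)
    }
    h <- m$children$bottleneck$fw(h, training)
    for (j in rev(seq_len(m$depth))) {
      h <- m$children[[paste0("up", j)]]$fw(h, training)
      h <- op_concat_c(list(skips[[j]], h))
      h <- m$children[[paste0("dec", j)]]$fw(h, training)
    }
    op_sigmoid(m$children$head$fw(h, training))
  }
  m
}

# ---- UNet with ACB, multi-scale skips and channel attention --------------

# Decoder level j (j < M) fuses two branches:
#  A: shallower encoder maps max-pooled to level-j resolution (1x1-projected
#     to the level width) summed with the same-level encoder map, then ACB;
#  B: deeper decoder maps brought up to level-j resolution by chains of
#     transposed convolutions, summed, then ACB;
# [A, B] is concatenated and a channel attention block emits the level map.
build_acb_unet <- function(cfg) {
  act <- cfg$activation
  w <- cfg$widths
  M <- length(w)
  m <- new_module("acb_unet")
  cin <- cfg$in_channels
  for (j in seq_len(M)) {
    mod_child(m, paste0("enc", j), acb_block(cin, w[j], act))
    cin <- w[j]
  }
  for (j in seq_len(M - 1L)) {
    for (k in seq_len(j - 1L)) {
      mod_child(m, paste0("down", k, "_", j), layer_conv(1L, 1L, w[k], w[j], bias = FALSE))
    }
    for (k in (j + 1L):M) {
      steps <- k - j
      cins <- c(w[k], rep(w[j], steps - 1L))
      for (s in seq_len(steps)) {
        mod_child(m, paste0("up", k, "_", j, "_", s), layer_convT2(cins[s], w[j]))
      }
    }
    mod_child(m, paste0("accA", j), acb_block(w[j], w[j], act))
    mod_child(m, paste0("accB", j), acb_block(w[j], w[j], act))
    mod_child(m, paste0("chab", j), chab_block(2L * w[j], w[j], 16L, act))
  }
  mod_child(m, "head", layer_conv(1L, 1L, w[1L], 1L))
  m$levels <- M
  m$fw <- function(x, training = FALSE) {
    enc <- vector("list", M)
    h <- x
    for (j in seq_len(M)) {
      if (j > 1L) h <- op_maxpool2(h)
      h <- m$children[[paste0("enc", j)]]$fw(h, training)
      enc[[j]] <- h
    }
    dec <- vector("list", M)
    dec[[M]] <- enc[[M]]
    for (j in seq(M - 1L, 1L)) {
      a <- enc[[j]]
      for (k in seq_len(j - 1L)) {
        p <- enc[[k]]
        for (s in seq_len(j - k)) p <- op_maxpool2(p)
        a <- op_add(a, m$children[[paste0("down", k, "_", j)]]$fw(p, training))
      }
      a <- m$children[[paste0("accA", j)]]$fw(a, training)
      b <- NULL
      for (k in (j + 1L):M) {
        p <- dec[[k]]
        for (s in seq_len(k - j)) {
          p <- m$children[[paste0("up", k, "_", j, "_", s)]]$fw(p, training)
        }
        b <- if (is.null(b)) p else op_add(b, p)
      }
      b <- m$children[[paste0("accB", j)]]$fw(b, training)
      dec[[j]] <- m$children[[paste0("chab", j)]]$fw(op_concat_c(list(a, b)), training)
    }
    op_sigmoid(m$children$head$fw(dec[[1L]], training))
  }
  m
}

# ---- ResNet-34 FPN with linear attention ---------------------------------

res_basic_block <- function(cin, cout, stride, act) {
  m <- new_module("res_block")
  mod_child(m, "c1", layer_conv(3L, 3L, cin, cout, stride = stride, bias = FALSE))
  mod_child(m, "bn1", layer_bn(cout))
  mod_child(m, "c2", layer_conv(3L, 3L, cout, cout, bias = FALSE))
  mod_child(m, "bn2", layer_bn(cout))
  if (stride != 1L || cin != cout) {
    mod_child(m, "down", layer_conv(1L, 1L, cin, cout, stride = stride, bias = FALSE))
    mod_child(m, "down_bn", layer_bn(cout))
  }
  m$fw <- function(x, training = FALSE) {
    h <- op_act(m$children$bn1$fw(m$children$c1$fw(x, training), training), act)
    h <- m$children$bn2$fw(m$children$c2$fw(h, training), training)
    sk <- if (!is.null(m$children$down)) {
      m$children$down_bn$fw(m$children$down$fw(x, training), training)
    } else x
    op_act(op_add(h, sk), act)
  }
  m
}

build_resnet34_backbone <- function(cfg) {
  act <- cfg$activation
  w <- cfg$widths  # stage widths (64, 128, 256, 512)
  reps <- c(3L, 4L, 6L, 3L)
  m <- new_module("resnet34")
  mod_child(m, "stem", layer_cba(7L, 7L, cfg$in_channels, w[1L], act, stride = 2L))
  for (st in seq_len(4L)) {
    cin <- if (st == 1L) w[1L] else w[st - 1L]
    for (r in seq_len(reps[st])) {
      stride <- if (st > 1L && r == 1L) 2L else 1L
      mod_child(m, paste0("s", st, "b", r),
                res_basic_block(if (r == 1L) cin else w[st], w[st], stride, act))
    }
  }
  m$reps <- reps
  m$fw <- function(x, training = FALSE) {
    h <- op_maxpool2(m$children$stem$fw(x, training))
    feats <- vector("list", 4L)
    for (st in seq_len(4L)) {
      for (r in seq_len(m$reps[st])) {
        h <- m$children[[paste0("s", st, "b", r)]]$fw(h, training)
      }
      feats[[st]] <- h
    }
    feats  # F2..F5 at 1/4, 1/8, 1/16, 1/32 of the input
  }
  m
}

build_fpn_topdown <- function(widths, d) {
  m <- new_module("fpn_topdown")
  for (i in 2:5) {
    mod_child(m, paste0("lat", i), layer_conv(1L, 1L, widths[i - 1L], d))
    mod_child(m, paste0("smooth", i), layer_conv(3L, 3L, d, d))
  }
  m$fw <- function(feats, training = FALSE) {
    mm <- vector("list", 4L)  # M2..M5
    mm[[4L]] <- m$children$lat5$fw(feats[[4L]], training)
    for (i in 3:1) {
      mm[[i]] <- op_add(m$children[[paste0("lat", i + 1L)]]$fw(feats[[i]], training),
                        op_upsample(mm[[i + 1L]], 2L, "nearest"))
    }
    lapply(1:4, function(i) m$children[[paste0("smooth", i + 1L)]]$fw(mm[[i]], training))
  }
  m
}

build_fpn_la <- function(cfg) {
  act <- cfg$activation
  d <- cfg$pyramid_width
  m <- new_module("fpn_la")
  mod_child(m, "backbone", build_resnet34_backbone(cfg))
  mod_child(m, "topdown", build_fpn_topdown(cfg$widths, d))
  mod_child(m, "agg", attention_aggregation(d))
  mod_child(m, "head_conv", layer_conv(3L, 3L, 4L * d, d))
  mod_child(m, "head_out", layer_conv(1L, 1L, d, 1L))
  m$fw <- function(x, training = FALSE) {
    feats <- m$children$backbone$fw(x, training)
    ps <- m$children$topdown$fw(feats, training)
    agg <- m$children$agg$fw(ps, training)
    h <- op_act(m$children$head_conv$fw(agg, training), act)
    h <- op_upsample(h, 4L, "bilinear")
    op_sigmoid(m$children$head_out$fw(h, training))
  }
  m
}

#' Build a segmentation model
#'
#' Instantiates one of the three architectures with seeded random weights.
#'
#' @param config a [model_config()].
#' @return a `nodseg_model` object; run it with [predict_model()] or train it
#'   with [train_model()].
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "nodseg_model_config"))
  old <- globalenv()$.Random.seed
  set.seed(config$seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  net <- switch(config$architecture,
    msunet = build_msunet(config),
    acb_unet = build_acb_unet(config),
    fpn_la = build_fpn_la(config))
  structure(list(net = net, config = config), class = "nodseg_model")
}

#' @export
print.nodseg_model <- function(x, ...) {
  cat("<nodseg_model>", x$config$architecture,
      "| activation:", x$config$activation$name,
      "| parameters:", format(n_params(x$net), big.mark = ","), "\n")
  invisible(x)
}

check_model_input <- function(model, x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  div <- switch(model$config$architecture,
    msunet = 2L^length(model$config$widths),
    acb_unet = 2L^(length(model$config$widths) - 1L),
    fpn_la = 32L)
  if (d[1L] %% div != 0 || d[2L] %% div != 0) {
    stop("input spatial size ", d[1L], "x", d[2L],
         " must be divisible by ", div, " for ", model$config$architecture)
  }
  x
}

#' Forward pass of a segmentation model
#'
#' @param model a `nodseg_model`.
#' @param x input images: a numeric `(H, W)` matrix, `(H, W, 1)` or
#'   `(H, W, 1, N)` array.
#' @param training use batch statistics in normalization layers (and update
#'   their running estimates); `FALSE` for deterministic evaluation.
#' @return probability maps in `(0, 1)`, same spatial size as the input,
#'   as an `(H, W, 1, N)` array.
#' @export
predict_model <- function(model, x, training = FALSE) {
  x <- check_model_input(model, x)
  model$net$fw(ag_const(x), training = training)$v
}

#' Extract bottom-up pyramid features (fpn_la only)
#'
#' @param model a `nodseg_model` with architecture `"fpn_la"`.
#' @param x input image array.
#' @return list of arrays `F2..F5` at 1/4, 1/8, 1/16 and 1/32 of the input
#'   spatial size.
#' @export
fpn_bottom_up <- function(model, x) {
  stopifnot(model$config$architecture == "fpn_la")
  x <- check_model_input(model, x)
  lapply(model$net$children$backbone$fw(ag_const(x)), function(t) t$v)
}

#' Top-down pyramid maps P2..P5 (fpn_la only)
#'
#' @inheritParams fpn_bottom_up
#' @return list of arrays `P2..P5`, each with `pyramid_width` channels.
#' @export
fpn_top_down <- function(model, x) {
  stopifnot(model$config$architecture == "fpn_la")
  x <- check_model_input(model, x)
  feats <- model$net$children$backbone$fw(ag_const(x))
  lapply(model$net$children$topdown$fw(feats), function(t) t$v)
}
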