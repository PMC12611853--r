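# Training and evaluation: Adam with L2 weight decay, seeded shuffling,
# per-epoch train/validation history, best-checkpoint retention.

#' Training configuration
#'
#' @param epochs number of passes over the training partition.
#' @param batch_size images per gradient step.
#' @param learning_rate,weight_decay Adam step size and L2 penalty.
#' @param w_bce,w_dice BCE-Dice loss weights (sum to 1).
#' @param smooth Dice smoothing constant.
#' @param threshold probability binarization threshold for evaluation.
#' @param seed seed controlling batch shuffling.
#' @return a `nodseg_train_config` list.
#' @export
train_config <- function(epochs = 200L, batch_size = 8L,
                         learning_rate = 1e-5, weight_decay = 1e-4,
                         w_bce = 0.5, w_dice = 0.5, smooth = 1.0,
                         threshold = 0.5, seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0, weight_decay >= 0,
            smooth > 0, threshold >= 0, threshold <= 1)
  if (abs(w_bce + w_dice - 1) > 1e-9) stop("w_bce + w_dice must equal 1")
  structure(as.list(environment()), class = "nodseg_train_config")
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) numeric(length(p$v))),
       v = lapply(params, function(p) numeric(length(p$v))))
}

adam_step <- function(params, state, t, lr, wd, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  cpp_adam_step(unname(params), state$m, state$v, as.integer(t),
                lr, wd, beta1, beta2, eps)
  state
}

# Stack a list of phantom samples into (H,W,1,B) image and mask arrays.
stack_batch <- function(samples, standardize_images = TRUE) {
  h <- nrow(samples[[1L]]$image)
  w <- ncol(samples[[1L]]$image)
  n <- length(samples)
  x <- array(0, c(h, w, 1L, n))
  y <- array(0, c(h, w, 1L, n))
  for (i in seq_len(n)) {
    img <- samples[[i]]$image
    if (standardize_images) img <- standardize(img)
    x[, , 1L, i] <- img
    y[, , 1L, i] <- samples[[i]]$nodule_mask
  }
  list(x = x, y = y)
}

batch_loss <- function(model, batch, config, training = TRUE, backward = FALSE) {
  xt <- ag_const(batch$x)
  pred <- model$net$fw(xt, training = training)
  loss <- op_bce_dice(pred, batch$y, config$w_bce, config$w_dice, config$smooth)
  if (backward) ag_backward(loss)
  as.numeric(loss$v)
}

#' Train a segmentation model
#'
#' Runs Adam (L2 weight decay folded into the gradient) on the BCE-Dice
#' loss with seeded epoch shuffling. Per-epoch mean training loss and,
#' when a validation partition is given, validation loss / DSC / IoU are
#' recorded; the parameter state with the best validation DSC is restored
#' at the end (with no validation set the final state is kept).
#'
#' @param model a `nodseg_model` from [build_model()].
#' @param train_data list of samples, each with `$image` and `$nodule_mask`.
#' @param val_data optional validation samples in the same format.
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return a `nodseg_fit` list: the trained `model`, the `history` data
#'   frame (epoch, train_loss, val_loss, val_dsc, val_iou) and `config`.
#' @export
train_model <- function(model, train_data, val_data = NULL,
                        config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "nodseg_model"), length(train_data) >= 1)
  params <- collect_params(model$net)
  state <- adam_state(params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_dsc = numeric(),
                        val_iou = numeric())
  if (config$epochs == 0L) {
    return(structure(list(model = model, history = history, config = config),
                     class = "nodseg_fit"))
  }
  old_seed <- globalenv()$.Random.seed
  set.seed(config$seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  best_dsc <- -Inf
  best_state <- NULL
  t <- 0L
  n <- length(train_data)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
      batch <- stack_batch(train_data[idx])
      ag_zero_grad(params)
      losses[bi] <- batch_loss(model, batch, config, training = TRUE, backward = TRUE)
      if (!is.finite(losses[bi])) {
        stop("training diverged: non-finite loss at epoch ", epoch, ", batch ", bi)
      }
      t <- t + 1L
      state <- adam_step(params, state, t, config$learning_rate, config$weight_decay)
    }
    vl <- vd <- vi <- NA_real_
    if (!is.null(val_data) && length(val_data)) {
      vb <- stack_batch(val_data)
      vl <- batch_loss(model, vb, config, training = FALSE)
      rep_ <- evaluate_model(model, val_data, threshold = config$threshold)
      vd <- rep_$mean$dsc
      vi <- rep_$mean$iou
      if (vd > best_dsc) {
        best_dsc <- vd
        best_state <- module_state(model$net)
      }
    }
    history[epoch, ] <- list(epoch, mean(losses), vl, vd, vi)
    if (verbose) {
      message(sprintf("epoch %3d  train loss %.5f  val loss %s  val DSC %s",
                      epoch, mean(losses),
                      ifelse(is.na(vl), "-", sprintf("%.5f", vl)),
                      ifelse(is.na(vd), "-", sprintf("%.4f", vd))))
    }
  }
  if (!is.null(best_state)) module_load_state(model$net, best_state)
  structure(list(model = model, history = history, config = config),
            class = "nodseg_fit")
}

#' @export
print.nodseg_fit <- function(x, ...) {
  h <- x$history
  cat("<nodseg_fit>", x$model$config$architecture, "|", nrow(h), "epochs\n")
  if (nrow(h)) {
    cat(sprintf("  train loss %.5f -> %.5f\n", h$train_loss[1L], h$train_loss[nrow(h)]))
    if (!all(is.na(h$val_dsc))) {
      cat(sprintf("  best val DSC %.4f\n", max(h$val_dsc, na.rm = TRUE)))
    }
  }
  invisible(x)
}

#' @export
plot.nodseg_fit <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) return(invisible(x))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "BCE-Dice loss", ...)
  if (!all(is.na(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Evaluate a model on a sample set
#'
#' Predictions are binarized at `threshold`; the five overlap metrics are
#' computed per image and averaged (unweighted mean over images).
#'
#' @param model a `nodseg_model` (or a `nodseg_fit`, whose model is used).
#' @param data list of samples with `$image` and `$nodule_mask`.
#' @param threshold probability binarization threshold.
#' @param batch_size forward-pass batch size.
#' @return list with `mean` (named list of the five averaged metrics),
#'   `per_image` (data frame, one row per image) and `n`.
#' @export
evaluate_model <- function(model, data, threshold = 0.5, batch_size = 8L) {
  if (inherits(model, "nodseg_fit")) model <- model$model
  if (!length(data)) stop("empty evaluation set")
  rows <- vector("list", length(data))
  starts <- seq(1L, length(data), by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, length(data))
    batch <- stack_batch(data[idx])
    pred <- predict_model(model, batch$x)
    for (j in seq_along(idx)) {
      pm <- (pred[, , 1L, j] >= threshold) * 1L
      met <- compute_metrics(confusion_counts(pm, batch$y[, , 1L, j]))
      rows[[idx[j]]] <- data.frame(
        image = idx[j], precision = met$precision, recall = met$recall,
        accuracy = met$accuracy, dsc = met$dsc, iou = met$iou,
        degenerate = any(met$degenerate))
    }
  }
  per_image <- do.call(rbind, rows)
  mean_m <- lapply(per_image[c("precision", "recall", "accuracy", "dsc", "iou")], mean)
  list(mean = mean_m, per_image = per_image, n = length(data))
}

#' Split indices into train / validation / test partitions
#'
#' Partition sizes are the fractions of `n` rounded to integers (largest
#' remainder rule, so sizes always sum to `n`); membership is a seeded
#' shuffle, and the three partitions are disjoint.
#'
#' @param n number of items (or a list of items, whose length is used).
#' @param fractions positive length-3 vector summing to 1.
#' @param seed shuffle seed.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (is.list(n)) n <- length(n)
  if (length(fractions) != 3L || any(fractions <= 0)) {
    stop("fractions must be three positive numbers")
  }
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  sizes <- floor(n * fractions)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(n * fractions - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  if (any(sizes < 1)) {
    stop("n = ", n, " too small: every partition needs at least one sample")
  }
  old_seed <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  ord <- sample.int(n)
  list(train = sort(ord[seq_len(sizes[1L])]),
       val = sort(ord[sizes[1L] + seq_len(sizes[2L])]),
       test = sort(ord[sizes[1L] + sizes[2L] + seq_len(sizes[3L])]))
}

#' Save / load a model checkpoint
#'
#' The parameter state (including batch-norm running statistics) is written
#' with `saveRDS`, alongside a JSON sidecar describing the architecture
#' configuration.
#'
#' @param model a `nodseg_model` or `nodseg_fit`.
#' @param path checkpoint path (`.rds`); the sidecar is `<path>.json`.
#' @return `save_model` the path, invisibly; `load_model` a `nodseg_model`.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "nodseg_fit")) model <- model$model
  cfg <- model$config
  saveRDS(list(state = module_state(model$net),
               config = cfg[c("architecture", "in_channels", "pyramid_width",
                              "widths", "seed")],
               activation = cfg$activation$name,
               activation_params = cfg$activation$params,
               format_version = 1L),
          path)
  jsonlite::write_json(
    list(format_version = 1L, architecture = cfg$architecture,
         in_channels = cfg$in_channels, pyramid_width = cfg$pyramid_width,
         widths = cfg$widths, activation = cfg$activation$name),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @param path checkpoint path written by [save_model()].
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  act <- activation(ck$activation,
                    slope = ck$activation_params$slope,
                    alpha = ck$activation_params$alpha,
                    tanh_approx = ck$activation_params$tanh_approx)
  cfg <- model_config(architecture = ck$config$architecture,
                      in_channels = ck$config$in_channels,
                      activation = act,
                      pyramid_width = ck$config$pyramid_width,
                      widths = ck$config$widths,
                      seed = ck$config$seed)
  model <- build_model(cfg)
  module_load_state(model$net, ck$state)
  model
}
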