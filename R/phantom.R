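# Synthetic thorax phantoms: a bright body ellipse containing two dark,
# vertically elongated lung fields with 0-5 brighter elliptical nodules
# placed strictly inside the lungs, plus additive Gaussian noise. Every
# downstream stage (preprocessing, training, evaluation) is exercisable on
# these phantoms without any external data.

with_seed <- function(seed, code) {
  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Phantom generator configuration
#'
#' Intensities emulate a soft-tissue-windowed CT slice on a 0-1 grayscale:
#' near-black air background, dark lung parenchyma, bright soft-tissue body
#' and nodules of almost soft-tissue density sitting inside the dark lungs.
#'
#' @param image_size pixels per side (square slice, >= 32).
#' @param n_nodules_range inclusive integer range for the nodule count.
#' @param nodule_radius_range nodule radius range in pixels.
#' @param lung_intensity,body_intensity,nodule_intensity,background_intensity
#'   grayscale means; must satisfy background < lung < nodule <= body.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param juxtapleural allow nodules to touch the lung boundary (off by
#'   default so connected-component counts stay exact).
#' @param seed integer seed; the sample is a deterministic function of it.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(image_size = 128L,
                           n_nodules_range = c(0L, 5L),
                           nodule_radius_range = c(2, 8),
                           lung_intensity = 0.18,
                           body_intensity = 0.70,
                           nodule_intensity = 0.65,
                           background_intensity = 0.02,
                           noise_sigma = 0.04,
                           juxtapleural = FALSE,
                           seed = 1L) {
  if (image_size < 32L) stop("image_size must be at least 32")
  if (any(nodule_radius_range <= 0)) stop("nodule radii must be positive")
  if (n_nodules_range[1L] > n_nodules_range[2L] || any(n_nodules_range < 0)) {
    stop("invalid n_nodules_range")
  }
  if (!(background_intensity < lung_intensity &&
        lung_intensity < nodule_intensity &&
        nodule_intensity <= body_intensity)) {
    stop("intensities must satisfy background < lung < nodule <= body")
  }
  structure(list(image_size = as.integer(image_size),
                 n_nodules_range = as.integer(n_nodules_range),
                 nodule_radius_range = nodule_radius_range,
                 lung_intensity = lung_intensity,
                 body_intensity = body_intensity,
                 nodule_intensity = nodule_intensity,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma,
                 juxtapleural = juxtapleural,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

ellipse_mask <- function(s, cr, cc, ar, ac, theta = 0) {
  r <- matrix(seq_len(s) - 1, s, s) - cr
  c <- matrix(seq_len(s) - 1, s, s, byrow = TRUE) - cc
  if (theta != 0) {
    rr <- r * cos(theta) + c * sin(theta)
    cc2 <- -r * sin(theta) + c * cos(theta)
    r <- rr; c <- cc2
  }
  ((r / ar)^2 + (c / ac)^2 <= 1) * 1L
}

phantom_geometry <- function(s) {
  list(body = list(cr = 0.50 * s, cc = 0.50 * s, ar = 0.42 * s, ac = 0.45 * s),
       lungs = list(
         list(cr = 0.50 * s, cc = 0.31 * s, ar = 0.30 * s, ac = 0.15 * s),
         list(cr = 0.50 * s, cc = 0.69 * s, ar = 0.30 * s, ac = 0.15 * s)))
}

#' Generate one thorax phantom
#'
#' Deterministic in `config$seed`. The returned nodule mask is a pixelwise
#' subset of the lung mask; with the default disjoint placement the number
#' of 8-connected components of the nodule mask equals `n_nodules`.
#'
#' @param config a [phantom_config()].
#' @return a `phantom_sample` list: `image` (numeric matrix), `lung_mask`
#'   and `nodule_mask` (0/1 integer matrices), `n_nodules`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  s <- config$image_size
  geo <- phantom_geometry(s)
  min_semi <- 0.15 * s
  if (min(config$nodule_radius_range) >= min_semi) {
    stop("lung fields (semi-minor axis ", round(min_semi, 1),
         " px) cannot fit nodules of radius >= ", min(config$nodule_radius_range))
  }
  with_seed(config$seed, {
    lung <- ellipse_mask(s, geo$lungs[[1]]$cr, geo$lungs[[1]]$cc,
                         geo$lungs[[1]]$ar, geo$lungs[[1]]$ac) |
            ellipse_mask(s, geo$lungs[[2]]$cr, geo$lungs[[2]]$cc,
                         geo$lungs[[2]]$ar, geo$lungs[[2]]$ac)
    lung <- lung * 1L
    body <- ellipse_mask(s, geo$body$cr, geo$body$cc, geo$body$ar, geo$body$ac)
    n_nod <- if (config$n_nodules_range[1L] == config$n_nodules_range[2L]) {
      config$n_nodules_range[1L]
    } else {
      sample(config$n_nodules_range[1L]:config$n_nodules_range[2L], 1L)
    }
    interior <- if (config$juxtapleural) lung else {
      cpp_erode(lung, structuring_element("square", 1L))
    }
    nodule <- matrix(0L, s, s)
    placed <- 0L
    attempts <- 0L
    while (placed < n_nod) {
      attempts <- attempts + 1L
      if (attempts > 500L) {
        stop("could not place ", n_nod, " disjoint nodules of radius ",
             config$nodule_radius_range[1L], "-", config$nodule_radius_range[2L],
             " inside the lung fields")
      }
      r <- stats::runif(1, config$nodule_radius_range[1L], config$nodule_radius_range[2L])
      lg <- geo$lungs[[sample(1:2, 1L)]]
      cr <- stats::runif(1, lg$cr - lg$ar, lg$cr + lg$ar)
      cc <- stats::runif(1, lg$cc - lg$ac, lg$cc + lg$ac)
      cand <- ellipse_mask(s, cr, cc, r, r * stats::runif(1, 0.6, 1),
                           theta = stats::runif(1, 0, pi))
      if (!any(cand == 1L)) next
      if (any(cand == 1L & interior == 0L)) next
      if (placed > 0L) {
        grown <- cpp_dilate(nodule, structuring_element("square", 1L))
        if (any(cand == 1L & grown == 1L)) next
      }
      nodule <- pmax(nodule, cand)
      placed <- placed + 1L
    }
    img <- matrix(config$background_intensity, s, s)
    img[body == 1L] <- config$body_intensity
    img[lung == 1L] <- config$lung_intensity
    img[nodule == 1L] <- config$nodule_intensity
    if (config$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(s * s, sd = config$noise_sigma), s, s)
    }
    structure(list(image = img, lung_mask = lung,
                   nodule_mask = matrix(as.integer(nodule), s, s),
                   n_nodules = n_nod, config = config),
              class = "phantom_sample")
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat("<phantom_sample>", nrow(x$image), "x", ncol(x$image),
      "|", x$n_nodules, "nodule(s) | lung area",
      sum(x$lung_mask), "px\n")
  invisible(x)
}

sample_seed <- function(base, i) {
  as.integer((as.numeric(base) * 1009 + i * 7919) %% 2147483647)
}

#' Generate a partitioned phantom dataset
#'
#' Generates `n` phantoms (each deterministic in the base seed and its
#' index) and partitions them into disjoint train / validation / test sets
#' by a seeded shuffle; partition sizes are the rounded fractions of `n`.
#'
#' @param n number of phantoms (must allow at least one per partition).
#' @param config a [phantom_config()]; its `seed` drives generation and the
#'   split shuffle.
#' @param split_fractions positive length-3 vector summing to 1.
#' @return list with `train`, `val`, `test` (lists of `phantom_sample`) and
#'   `indices` (the partition of `1:n`).
#' @export
generate_phantom_dataset <- function(n, config = phantom_config(),
                                     split_fractions = c(0.8, 0.1, 0.1)) {
  idx <- split_dataset(n, split_fractions, seed = config$seed)
  samples <- lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- sample_seed(config$seed, i)
    generate_phantom(cfg)
  })
  list(train = samples[idx$train], val = samples[idx$val],
       test = samples[idx$test], indices = idx)
}

#' Write phantoms as PNG pairs with a manifest
#'
#' Writes `image_####.png`, `lung_####.png`, `nodule_####.png` per sample
#' plus a tab-separated `manifest.tsv` (index, n_nodules, file names).
#'
#' @param samples list of `phantom_sample` objects.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_phantom_dataset <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    smp <- samples[[i]]
    fi <- sprintf("image_%04d.png", i)
    fl <- sprintf("lung_%04d.png", i)
    fn <- sprintf("nodule_%04d.png", i)
    png::writePNG(pmin(pmax(smp$image, 0), 1), file.path(dir, fi))
    write_mask(smp$lung_mask, file.path(dir, fl))
    write_mask(smp$nodule_mask, file.path(dir, fn))
    rows[[i]] <- data.frame(index = i, n_nodules = smp$n_nodules,
                            image = fi, lung_mask = fl, nodule_mask = fn)
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
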