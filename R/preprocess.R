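# CT preprocessing chain: standardization, median + anisotropic-diffusion
# filtering, K-means thresholding of intensities, morphological opening,
# lung-region selection, ROI extraction, and rasterization of reader
# contour annotations into consensus nodule masks.

#' Standardize an image to zero mean, unit variance
#'
#' Uses the population standard deviation. A constant image (zero spread)
#' is rejected as degenerate.
#'
#' @param image numeric matrix.
#' @return matrix with mean 0 and population standard deviation 1.
#' @export
standardize <- function(image) {
  mu <- mean(image)
  sd_pop <- sqrt(mean((image - mu)^2))
  if (sd_pop == 0) stop("degenerate input: constant image has zero standard deviation")
  (image - mu) / sd_pop
}

#' Median filter with reflection padding
#'
#' @param image numeric matrix.
#' @param window odd window side length; `1` is the identity.
#' @return filtered matrix of the same shape.
#' @export
median_filter <- function(image, window = 3L) {
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  if (window == 1L) return(image)
  cpp_median_filter(image, as.integer(window))
}

#' Anisotropic diffusion parameters
#'
#' @param n_iterations number of explicit update steps (>= 0).
#' @param kappa edge-stopping conductance scale (> 0); gradients well below
#'   `kappa` diffuse freely, gradients above it are preserved as edges.
#' @param gamma step size per iteration; must lie in (0, 0.25], the
#'   stability bound of the explicit 4-neighbour scheme.
#' @param conduction `"exponential"` (`exp(-(g/kappa)^2)`) or `"rational"`
#'   (`1/(1+(g/kappa)^2)`).
#' @return a `diffusion_params` list.
#' @export
diffusion_params <- function(n_iterations = 10L, kappa = 30, gamma = 0.1,
                             conduction = c("exponential", "rational")) {
  conduction <- match.arg(conduction)
  if (n_iterations < 0) stop("n_iterations must be >= 0")
  if (kappa <= 0) stop("kappa must be positive")
  if (gamma <= 0 || gamma > 0.25) {
    stop("gamma must lie in (0, 0.25] for stability of the 4-neighbour scheme")
  }
  structure(list(n_iterations = as.integer(n_iterations), kappa = kappa,
                 gamma = gamma, conduction = conduction),
            class = "diffusion_params")
}

#' Perona-Malik anisotropic diffusion
#'
#' Explicit iterations of edge-preserving diffusion with 4-neighbour
#' gradients and zero-flux (replicated-edge) boundaries: homogeneous areas
#' are smoothed while gradients on the order of `kappa` or larger are kept.
#'
#' @param image numeric matrix.
#' @param params a [diffusion_params()].
#' @return diffused matrix of the same shape.
#' @export
anisotropic_diffusion <- function(image, params = diffusion_params()) {
  stopifnot(inherits(params, "diffusion_params"))
  cond <- if (params$conduction == "exponential") {
    function(g) exp(-(g / params$kappa)^2)
  } else {
    function(g) 1 / (1 + (g / params$kappa)^2)
  }
  x <- image
  h <- nrow(x); w <- ncol(x)
  for (it in seq_len(params$n_iterations)) {
    gn <- x[c(1L, seq_len(h - 1L)), , drop = FALSE] - x
    gs <- x[c(seq_len(h - 1L) + 1L, h), , drop = FALSE] - x
    gw <- x[, c(1L, seq_len(w - 1L)), drop = FALSE] - x
    ge <- x[, c(seq_len(w - 1L) + 1L, w), drop = FALSE] - x
    x <- x + params$gamma *
      (cond(gn) * gn + cond(gs) * gs + cond(gw) * gw + cond(ge) * ge)
  }
  x
}

#' K-means intensity thresholding
#'
#' Clusters pixel intensities with 1-D K-means (Euclidean distance,
#' k-means++-style multiple restarts) and labels as foreground (1) the
#' pixels assigned to cluster(s) whose centers lie below the inter-cluster
#' threshold, taken as the midpoint of the largest gap between sorted
#' cluster centers. For CT slices the low-intensity clusters are air and
#' lung parenchyma.
#'
#' @param image numeric matrix with at least `k` distinct values.
#' @param k number of clusters (>= 2).
#' @param seed seed for the restarts (result is deterministic given it).
#' @return 0/1 integer matrix, same shape as `image`.
#' @export
kmeans_threshold <- function(image, k = 2L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  vals <- unique(as.vector(image))
  if (length(vals) < k) {
    stop("image has only ", length(vals), " distinct intensities; need >= k = ", k)
  }
  km <- with_seed(seed, stats::kmeans(as.vector(image), centers = k,
                                      nstart = 10L, iter.max = 100L))
  centers <- as.vector(km$centers)
  sc <- sort(centers)
  gaps <- diff(sc)
  gi <- which.max(gaps)
  thr <- (sc[gi] + sc[gi + 1L]) / 2
  low <- which(centers < thr)
  mask <- matrix(as.integer(km$cluster %in% low), nrow(image), ncol(image))
  mask
}

#' Structuring elements for binary morphology
#'
#' @param shape `"disk"`, `"square"` or `"cross"`.
#' @param radius half-width in pixels; the element is `(2 radius + 1)`
#'   pixels per side and symmetric about its center.
#' @return logical matrix usable with [erode()], [dilate()] and
#'   [morphological_open()].
#' @export
structuring_element <- function(shape = c("disk", "square", "cross"), radius = 1L) {
  shape <- match.arg(shape)
  if (radius < 0) stop("radius must be >= 0")
  d <- 2L * radius + 1L
  i <- matrix(seq_len(d) - radius - 1L, d, d)
  j <- t(i)
  se <- switch(shape,
    disk = i^2 + j^2 <= radius^2,
    square = matrix(TRUE, d, d),
    cross = i == 0L | j == 0L)
  if (!any(se)) stop("empty structuring element")
  se
}

as_binary_int <- function(mask, what = "mask") {
  check_binary(mask, what)
  storage.mode(mask) <- "integer"
  mask
}

#' Binary erosion, dilation and opening
#'
#' Pixels outside the image are treated as background (0). Opening is
#' erosion followed by dilation with the same element; it removes
#' foreground structures smaller than the element and is idempotent and
#' anti-extensive.
#'
#' @param mask 0/1 binary matrix.
#' @param selem logical structuring element from [structuring_element()].
#' @return 0/1 integer matrix.
#' @export
erode <- function(mask, selem = structuring_element("disk", 1L)) {
  if (!any(selem)) stop("empty structuring element")
  cpp_erode(as_binary_int(mask), selem)
}

#' @rdname erode
#' @export
dilate <- function(mask, selem = structuring_element("disk", 1L)) {
  if (!any(selem)) stop("empty structuring element")
  cpp_dilate(as_binary_int(mask), selem)
}

#' @rdname erode
#' @export
morphological_open <- function(mask, selem = structuring_element("disk", 1L)) {
  dilate(erode(mask, selem), selem)
}

#' Connected-component labeling
#'
#' @param mask 0/1 binary matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of component labels (0 = background) with
#'   attribute `n`, the number of components.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  cpp_label(as_binary_int(mask), as.integer(connectivity))
}

#' Region-selection criteria for lung masking
#'
#' @param min_area_fraction minimum component area as a fraction of the
#'   image area (components below it are discarded).
#' @param border_margin components with any pixel within this many pixels
#'   of the image border are discarded (removes the air background).
#' @param max_regions number of largest surviving components kept (2 for
#'   the two lung fields).
#' @return a `region_criteria` list.
#' @export
region_criteria <- function(min_area_fraction = 0.005, border_margin = 2L,
                            max_regions = 2L) {
  if (min_area_fraction < 0 || min_area_fraction >= 1) {
    stop("min_area_fraction must lie in [0, 1)")
  }
  structure(list(min_area_fraction = min_area_fraction,
                 border_margin = as.integer(border_margin),
                 max_regions = as.integer(max_regions)),
            class = "region_criteria")
}

#' Select lung regions from a binary candidate mask
#'
#' Labels 8-connected components, removes those touching the border strip
#' (width `border_margin`) or smaller than `min_area_fraction` of the image
#' area, keeps the `max_regions` largest remaining components, and (by
#' default) fills interior holes - bright structures such as nodules and
#' vessels punch holes into the lung-candidate mask but belong to the lung
#' field.
#'
#' @param mask 0/1 binary matrix (air/lung candidates).
#' @param criteria a [region_criteria()].
#' @param fill_holes fill holes fully enclosed by a kept region.
#' @return 0/1 integer lung mask; all-zero (with a warning) when no
#'   component survives.
#' @export
select_lung_regions <- function(mask, criteria = region_criteria(),
                                fill_holes = TRUE) {
  mask <- as_binary_int(mask)
  h <- nrow(mask); w <- ncol(mask)
  lab <- label_components(mask, 8L)
  nlab <- attr(lab, "n")
  if (nlab == 0L) return(matrix(0L, h, w))
  areas <- tabulate(lab[lab > 0L], nbins = nlab)
  m <- min(criteria$border_margin, h, w)
  touching <- if (m > 0L) {
    strip <- c(lab[seq_len(m), ], lab[h + 1L - seq_len(m), ],
               lab[, seq_len(m)], lab[, w + 1L - seq_len(m)])
    unique(strip[strip > 0L])
  } else integer(0)
  keep <- setdiff(which(areas >= criteria$min_area_fraction * h * w), touching)
  if (!length(keep)) {
    warning("no lung region survived the selection criteria; returning empty mask")
    return(matrix(0L, h, w))
  }
  keep <- keep[order(areas[keep], decreasing = TRUE)][seq_len(min(criteria$max_regions, length(keep)))]
  out <- matrix(as.integer(lab %in% keep), h, w)
  if (fill_holes) {
    comp <- label_components(1L - out, 4L)
    border_bg <- unique(c(comp[1L, ], comp[h, ], comp[, 1L], comp[, w]))
    holes <- setdiff(seq_len(attr(comp, "n")), border_bg)
    if (length(holes)) out[comp %in% holes] <- 1L
  }
  out
}

#' Apply a lung mask to a CT slice
#'
#' The lung mask is dilated (adding a safety margin so juxtapleural
#' structures survive) and multiplied pixelwise with the slice; non-lung
#' pixels become 0.
#'
#' @param image numeric matrix.
#' @param lung_mask 0/1 binary matrix of the same shape.
#' @param dilation_selem structuring element for the margin dilation
#'   (`NULL` for none).
#' @return masked image (numeric matrix).
#' @export
apply_lung_mask <- function(image, lung_mask,
                            dilation_selem = structuring_element("disk", 5L)) {
  if (!identical(dim(image), dim(lung_mask))) stop("image / mask shape mismatch")
  m <- as_binary_int(lung_mask)
  if (!is.null(dilation_selem)) m <- cpp_dilate(m, dilation_selem)
  image * m
}

# ---- annotation rasterization --------------------------------------------

polygon_area <- function(pts) {
  r <- pts[, 1L]; c <- pts[, 2L]
  n <- nrow(pts)
  j <- c(n, seq_len(n - 1L))
  abs(sum(c * r[j] - c[j] * r)) / 2
}

# Fill a closed polygon given as 0-based (row, col) vertices into an
# H x W mask: even-odd scanline fill plus the rasterized outline, so
# boundary pixels are included.
fill_polygon <- function(shape, pts) {
  h <- shape[1L]; w <- shape[2L]
  out <- matrix(0L, h, w)
  n <- nrow(pts)
  rs <- pts[, 1L]; cs <- pts[, 2L]
  for (r in seq(max(0L, floor(min(rs))), min(h - 1L, ceiling(max(rs))))) {
    xs <- numeric(0)
    for (e in seq_len(n - 1L)) {
      r1 <- rs[e]; r2 <- rs[e + 1L]
      if ((r1 <= r && r2 > r) || (r2 <= r && r1 > r)) {
        xs <- c(xs, cs[e] + (r - r1) / (r2 - r1) * (cs[e + 1L] - cs[e]))
      }
    }
    xs <- sort(xs)
    for (p in seq_len(length(xs) %/% 2L)) {
      c1 <- ceiling(xs[2L * p - 1L]); c2 <- floor(xs[2L * p])
      if (c2 >= c1) out[r + 1L, max(1L, c1 + 1L):min(w, c2 + 1L)] <- 1L
    }
  }
  # outline
  for (e in seq_len(n - 1L)) {
    steps <- max(2L, ceiling(2 * max(abs(rs[e + 1L] - rs[e]), abs(cs[e + 1L] - cs[e]))) + 1L)
    t <- seq(0, 1, length.out = steps)
    ri <- round(rs[e] + t * (rs[e + 1L] - rs[e])) + 1L
    ci <- round(cs[e] + t * (cs[e + 1L] - cs[e])) + 1L
    ok <- ri >= 1L & ri <= h & ci >= 1L & ci <= w
    out[cbind(ri[ok], ci[ok])] <- 1L
  }
  out
}

#' Rasterize reader annotations into a consensus nodule mask
#'
#' Each reader's closed contours are filled into a per-reader binary map
#' (contours of nodules with equivalent diameter below `min_diameter_mm`
#' are excluded first); pixels marked by at least `consensus_fraction` of
#' the readers become nodule pixels.
#'
#' @param annotations an annotation set from [parse_annotations()] (or a
#'   list with the same structure).
#' @param shape `c(rows, cols)` of the target mask.
#' @param slice slice index whose contours are rasterized.
#' @param consensus_fraction fraction of readers required per pixel.
#' @param min_diameter_mm nodules below this equivalent diameter are
#'   ignored (the customary >= 3 mm rule).
#' @return 0/1 integer matrix.
#' @export
rasterize_annotations <- function(annotations, shape, slice = 0L,
                                  consensus_fraction = 0.5,
                                  min_diameter_mm = 3) {
  readers <- annotations$readers
  if (!length(readers)) return(matrix(0L, shape[1L], shape[2L]))
  votes <- matrix(0L, shape[1L], shape[2L])
  for (rd in readers) {
    rmask <- matrix(0L, shape[1L], shape[2L])
    for (ct in rd$contours) {
      if (!identical(as.integer(ct$slice), as.integer(slice))) next
      pts <- ct$points
      if (nrow(pts) < 4L || any(pts[1L, ] != pts[nrow(pts), ])) {
        stop("unclosed polygon in annotations of reader '", rd$id,
             "' (first and last vertex must coincide)")
      }
      if (any(pts[, 1L] < 0) || any(pts[, 2L] < 0) ||
          any(pts[, 1L] > shape[1L] - 1L) || any(pts[, 2L] > shape[2L] - 1L)) {
        stop("contour outside image bounds for reader '", rd$id, "'")
      }
      if (!is.null(ct$equiv_diameter_mm) && ct$equiv_diameter_mm < min_diameter_mm) next
      rmask <- pmax(rmask, fill_polygon(shape, pts))
    }
    votes <- votes + rmask
  }
  need <- consensus_fraction * length(readers)
  matrix(as.integer(votes >= need & votes > 0L), shape[1L], shape[2L])
}

# ---- full chain ----------------------------------------------------------

#' Preprocessing configuration
#'
#' @param hu_clamp length-2 range for clamping calibrated CT values (in
#'   Hounsfield units) before standardization; applied automatically only
#'   when the image looks HU-scaled (minimum below -500). `NULL` disables.
#' @param median_window odd median-filter window.
#' @param diffusion a [diffusion_params()].
#' @param kmeans_k,kmeans_seed K-means cluster count and seed.
#' @param opening_selem structuring element for the morphological opening.
#' @param criteria a [region_criteria()].
#' @param dilation_selem margin dilation applied when masking the slice.
#' @param fill_holes fill enclosed holes in the selected lung regions.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(hu_clamp = c(-1000, 400),
                              median_window = 3L,
                              diffusion = diffusion_params(),
                              kmeans_k = 2L, kmeans_seed = 1L,
                              opening_selem = structuring_element("disk", 2L),
                              criteria = region_criteria(),
                              dilation_selem = structuring_element("disk", 5L),
                              fill_holes = TRUE) {
  structure(list(hu_clamp = hu_clamp, median_window = median_window,
                 diffusion = diffusion, kmeans_k = kmeans_k,
                 kmeans_seed = kmeans_seed, opening_selem = opening_selem,
                 criteria = criteria, dilation_selem = dilation_selem,
                 fill_holes = fill_holes),
            class = "preprocess_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("preprocessing stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Segment the lung fields of a CT slice
#'
#' Runs the full chain: optional HU clamp, standardization, median filter,
#' anisotropic diffusion, K-means thresholding of intensities,
#' morphological opening, lung-region selection, and masking of the slice.
#'
#' @param image numeric matrix (raw grayscale or HU-calibrated).
#' @param config a [preprocess_config()].
#' @return list with `roi` (the masked slice) and `lung_mask` (0/1 matrix
#'   of the selected lung regions, before the ROI margin dilation).
#' @export
preprocess_slice <- function(image, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  x <- image
  if (!is.null(config$hu_clamp) && min(x) < -500) {
    x <- stage("hu_clamp", pmin(pmax(x, config$hu_clamp[1L]), config$hu_clamp[2L]))
  }
  x <- stage("standardize", standardize(x))
  x <- stage("median_filter", median_filter(x, config$median_window))
  x <- stage("anisotropic_diffusion", anisotropic_diffusion(x, config$diffusion))
  cand <- stage("kmeans_threshold",
                kmeans_threshold(x, config$kmeans_k, config$kmeans_seed))
  cand <- stage("morphological_open", morphological_open(cand, config$opening_selem))
  lung <- stage("select_lung_regions",
                select_lung_regions(cand, config$criteria, config$fill_holes))
  roi <- stage("apply_lung_mask", apply_lung_mask(image, lung, config$dilation_selem))
  list(roi = roi, lung_mask = lung)
}
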