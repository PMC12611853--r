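# Independent oracles used across the suite: they deliberately avoid the
# package's fast code paths (naive loops, double-sum formulations).

# Naive direct convolution (same semantics as the package kernels)
naive_conv <- function(x, w, stride = 1, ph = 0, pw = 0) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; N <- dim(x)[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Co <- dim(w)[4]
  Ho <- (H + 2 * ph - kh) / stride + 1
  Wo <- (W + 2 * pw - kw) / stride + 1
  y <- array(0, c(Ho, Wo, Co, N))
  for (n in 1:N) for (co in 1:Co) for (wo in 1:Wo) for (ho in 1:Ho) {
    s <- 0
    for (c in 1:C) for (dw in 1:kw) for (dh in 1:kh) {
      hi <- (ho - 1) * stride - ph + dh
      wi <- (wo - 1) * stride - pw + dw
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        s <- s + x[hi, wi, c, n] * w[dh, dw, c, co]
      }
    }
    y[ho, wo, co, n] <- s
  }
  y
}

# O(M^2) per-query double-sum form of linear attention
double_sum_attention <- function(Q, K, V, eps = 1e-6) {
  Qh <- Q / (sqrt(rowSums(Q^2)) + eps)
  Kh <- K / (sqrt(rowSums(K^2)) + eps)
  M <- nrow(Q)
  out <- matrix(0, M, ncol(V))
  for (x in seq_len(M)) {
    wts <- as.vector(1 + Kh %*% Qh[x, ])
    out[x, ] <- colSums(wts * V) / sum(wts)
  }
  out
}

# Recursive flood-fill count of 8-connected components (independent of the
# package's C++ labeling)
flood_count <- function(mask) {
  m <- mask != 0
  h <- nrow(m); w <- ncol(m)
  seen <- matrix(FALSE, h, w)
  count <- 0
  for (i0 in seq_len(h)) for (j0 in seq_len(w)) {
    if (!m[i0, j0] || seen[i0, j0]) next
    count <- count + 1
    stack <- list(c(i0, j0))
    seen[i0, j0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && m[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  count
}

# Set-theoretic morphology by pixel enumeration
naive_erode <- function(mask, se) {
  h <- nrow(mask); w <- ncol(mask)
  ah <- (nrow(se) - 1) / 2; aw <- (ncol(se) - 1) / 2
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    keep <- TRUE
    for (di in -ah:ah) for (dj in -aw:aw) {
      if (!se[di + ah + 1, dj + aw + 1]) next
      ii <- i + di; jj <- j + dj
      v <- if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) mask[ii, jj] else 0L
      if (v == 0L) keep <- FALSE
    }
    out[i, j] <- as.integer(keep)
  }
  out
}

naive_dilate <- function(mask, se) {
  h <- nrow(mask); w <- ncol(mask)
  ah <- (nrow(se) - 1) / 2; aw <- (ncol(se) - 1) / 2
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j] == 0L) next
    for (di in -ah:ah) for (dj in -aw:aw) {
      if (!se[di + ah + 1, dj + aw + 1]) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) out[ii, jj] <- 1L
    }
  }
  out
}

random_mask <- function(h, w, p = 0.4) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

mask_iou <- function(a, b) {
  u <- sum(a == 1L | b == 1L)
  if (u == 0) return(1)
  sum(a == 1L & b == 1L) / u
}

# Craft a minimal explicit-VR little-endian DICOM file
write_test_dicom <- function(path, img_values, rows, cols,
                             slope = 1, intercept = -1024, spacing = "0.7\\0.7") {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  elem <- function(group, el, vr, value_raw) {
    writeBin(as.integer(group), con, size = 2, endian = "little")
    writeBin(as.integer(el), con, size = 2, endian = "little")
    writeChar(vr, con, eos = NULL)
    if (vr %in% c("OB", "OW")) {
      writeBin(raw(2), con)
      writeBin(length(value_raw), con, size = 4, endian = "little")
    } else {
      writeBin(length(value_raw), con, size = 2, endian = "little")
    }
    writeBin(value_raw, con)
  }
  str_raw <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2) r <- c(r, as.raw(0x20))
    r
  }
  us_raw <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
  elem(0x0002, 0x0010, "UI", str_raw("1.2.840.10008.1.2.1"))
  elem(0x0010, 0x0020, "LO", str_raw("TESTPAT"))
  elem(0x0028, 0x0010, "US", us_raw(rows))
  elem(0x0028, 0x0011, "US", us_raw(cols))
  elem(0x0028, 0x0030, "DS", str_raw(spacing))
  elem(0x0028, 0x0100, "US", us_raw(16))
  elem(0x0028, 0x0103, "US", us_raw(0))
  elem(0x0028, 0x1052, "DS", str_raw(format(intercept)))
  elem(0x0028, 0x1053, "DS", str_raw(format(slope)))
  px <- writeBin(as.integer(img_values), raw(), size = 2, endian = "little")
  elem(0x7fe0, 0x0010, "OW", px)
  invisible(path)
}

# Small phantom dataset cache shared between tests
tiny_phantoms <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- lapply(1:6, function(i) {
        generate_phantom(phantom_config(image_size = 64L, seed = 400 + i))
      })
    }
    cache
  }
})
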