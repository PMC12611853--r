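# Readers and writers: PNG and NIfTI slices, a minimal reader for
# uncompressed little-endian DICOM (with HU conversion via rescale
# slope/intercept), binary mask output, and annotation parsing for a
# simplified JSON contour dialect plus best-effort LIDC-style XML.

#' Read a 2D CT slice
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"png"`, `"nifti"` or `"dicom"`.
#'   DICOM values are converted to Hounsfield units via the rescale slope
#'   and intercept when present (raw values, with a warning, otherwise).
#' @param slice_index slice to extract from a 3D NIfTI volume (1-based).
#' @return a `slice_record` list: `image` (numeric matrix), `spacing`
#'   (pixel spacing in mm, `NA` if unknown), `format`, `path`.
#' @export
read_slice <- function(path, format = c("auto", "png", "nifti", "dicom"),
                       slice_index = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext,
      png = "png", nii = "nifti", dcm = "dicom", dicom = "dicom",
      stop("unsupported slice format for '", path,
           "' (expected .png, .nii[.gz] or .dcm)"))
  }
  rec <- switch(format,
    png = {
      img <- png::readPNG(path)
      if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3L, dim(img)[3L])), drop = FALSE], c(1, 2), mean)
      list(image = unclass(img), spacing = NA_real_)
    },
    nifti = {
      vol <- RNifti::readNifti(path)
      spacing <- RNifti::pixdim(vol)[1L]
      img <- if (length(dim(vol)) >= 3L) vol[, , slice_index] else vol[, ]
      list(image = matrix(as.numeric(img), nrow(img), ncol(img)), spacing = spacing)
    },
    dicom = read_dicom_slice(path))
  structure(c(rec, list(format = format, path = path,
                        slice_index = as.integer(slice_index))),
            class = "slice_record")
}

# Minimal DICOM reader: uncompressed little-endian transfer syntaxes only.
read_dicom_slice <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_all) < 140L || rawToChar(raw_all[129:132]) != "DICM") {
    stop("'", path, "' is not a DICOM part-10 file")
  }
  pos <- 133L
  n <- length(raw_all)
  u16 <- function(at) sum(as.integer(raw_all[at:(at + 1L)]) * c(1L, 256L))
  str_at <- function(at, len) {
    b <- raw_all[at:(at + len - 1L)]
    trimws(rawToChar(b[b != as.raw(0L)]))
  }
  u32 <- function(at) sum(as.numeric(raw_all[at:(at + 3L)]) * c(1, 256, 65536, 16777216))
  explicit_body <- TRUE
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    in_meta <- group == 2L
    explicit <- in_meta || explicit_body
    if (explicit) {
      vr <- rawToChar(raw_all[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      len <- u32(pos + 4L); hdr <- 8L
      vr <- ""
    }
    if (len >= 4294967295) stop("undefined-length DICOM elements are not supported")
    val_at <- pos + hdr
    key <- sprintf("%04x,%04x", group, elem)
    if (key == "0002,0010") {
      ts <- str_at(val_at, len)
      if (ts == "1.2.840.10008.1.2") explicit_body <- FALSE
      else if (ts != "1.2.840.10008.1.2.1") {
        stop("unsupported DICOM transfer syntax '", ts, "' (uncompressed little-endian only)")
      }
    }
    tags[[key]] <- list(at = val_at, len = len, vr = vr)
    pos <- val_at + len
    if (key == "7fe0,0010") break
  }
  get_us <- function(key) if (is.null(tags[[key]])) NULL else u16(tags[[key]]$at)
  get_str <- function(key) {
    if (is.null(tags[[key]]) || tags[[key]]$len == 0L) return(NULL)
    str_at(tags[[key]]$at, tags[[key]]$len)
  }
  rows <- get_us("0028,0010"); cols <- get_us("0028,0011")
  if (is.null(rows) || is.null(cols)) stop("DICOM file lacks Rows/Columns")
  bits <- get_us("0028,0100"); if (is.null(bits)) bits <- 16L
  signed <- identical(get_us("0028,0103"), 1L)
  px <- tags[["7fe0,0010"]]
  if (is.null(px)) stop("DICOM file has no pixel data")
  vals <- readBin(raw_all[px$at:(px$at + px$len - 1L)], "integer",
                  n = rows * cols, size = bits %/% 8L, signed = signed || bits < 16L,
                  endian = "little")
  if (!signed && bits == 16L) vals <- ifelse(vals < 0, vals + 65536, vals)
  slope <- get_str("0028,1053"); intercept <- get_str("0028,1052")
  if (is.null(slope) || is.null(intercept)) {
    warning("DICOM rescale slope/intercept missing; using raw stored values")
    slope <- "1"; intercept <- "0"
  }
  img <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  img <- img * as.numeric(slope) + as.numeric(intercept)
  spacing <- get_str("0028,0030")
  spacing <- if (is.null(spacing)) NA_real_ else as.numeric(strsplit(spacing, "\\\\")[[1L]][1L])
  list(image = img, spacing = spacing,
       patient_id = get_str("0010,0020"), series_id = get_str("0020,000e"))
}

#' Write a binary mask
#'
#' PNG masks are written as 0/255 grayscale (viewer-friendly); NIfTI masks
#' keep 0/1. Both round-trip losslessly through [read_slice()] /
#' `RNifti::readNifti`.
#'
#' @param mask 0/1 binary matrix.
#' @param path output path ending in `.png` or `.nii`/`.nii.gz`.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  check_binary(mask)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "png") {
    png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  } else if (ext == "nii") {
    RNifti::writeNifti(RNifti::asNifti(matrix(as.numeric(mask), nrow(mask), ncol(mask))), path)
  } else {
    stop("unsupported mask format '", ext, "' (use .png or .nii[.gz])")
  }
  invisible(path)
}

contour_record <- function(slice, points, spacing_mm) {
  points <- matrix(as.numeric(points), ncol = 2L)
  area <- polygon_area(points)
  diam <- 2 * sqrt(area / pi) * spacing_mm
  list(slice = as.integer(slice), points = points,
       equiv_diameter_mm = diam, at_least_3mm = diam >= 3)
}

#' Parse nodule contour annotations
#'
#' Supports a simplified JSON dialect
#' (`{"readers": [{"id": ..., "contours": [{"slice": ..., "points": [[r, c], ...]}]}]}`,
#' coordinates 0-based `(row, col)`) and best-effort LIDC-style XML
#' (readingSession / unblindedReadNodule / roi / edgeMap elements; slices
#' are indexed by the rank of their z-position). Every contour gets an
#' equivalent diameter (circle of equal area, scaled by the pixel spacing);
#' sub-3 mm contours are retained but flagged, filtering happens at
#' rasterization time.
#'
#' @param path annotation file.
#' @param dialect `"auto"` (by extension), `"json"` or `"lidc_xml"`.
#' @param spacing_mm pixel spacing used for equivalent diameters.
#' @return an `annotation_set` list with one entry per reader.
#' @export
parse_annotations <- function(path, dialect = c("auto", "json", "lidc_xml"),
                              spacing_mm = 1) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (tolower(tools::file_ext(path)) == "xml") "lidc_xml" else "json"
  }
  readers <- if (dialect == "json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    lapply(doc$readers, function(rd) {
      list(id = rd$id,
           contours = lapply(rd$contours, function(ct) {
             pts <- do.call(rbind, lapply(ct$points, unlist))
             contour_record(ct$slice, pts, spacing_mm)
           }))
    })
  } else {
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    zpos <- sort(unique(as.numeric(xml2::xml_text(
      xml2::xml_find_all(doc, ".//roi/imageZposition")))))
    sessions <- xml2::xml_find_all(doc, ".//readingSession")
    lapply(seq_along(sessions), function(i) {
      ss <- sessions[[i]]
      id <- xml2::xml_text(xml2::xml_find_first(ss, "./servicingRadiologistID"))
      if (is.na(id) || id == "") id <- paste0("reader", i)
      rois <- xml2::xml_find_all(ss, ".//unblindedReadNodule/roi")
      contours <- lapply(rois, function(roi) {
        z <- as.numeric(xml2::xml_text(xml2::xml_find_first(roi, "./imageZposition")))
        xs <- as.numeric(xml2::xml_text(xml2::xml_find_all(roi, ".//edgeMap/xCoord")))
        ys <- as.numeric(xml2::xml_text(xml2::xml_find_all(roi, ".//edgeMap/yCoord")))
        pts <- cbind(ys, xs)
        if (nrow(pts) > 0L && any(pts[1L, ] != pts[nrow(pts), ])) {
          pts <- rbind(pts, pts[1L, ])  # LIDC edge maps list each vertex once
        }
        contour_record(match(z, zpos) - 1L, pts, spacing_mm)
      })
      list(id = id, contours = contours)
    })
  }
  structure(list(readers = readers, spacing_mm = spacing_mm),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set>", length(x$readers), "reader(s),",
      sum(vapply(x$readers, function(r) length(r$contours), numeric(1))),
      "contour(s)\n")
  invisible(x)
}

# ---- run configuration ----------------------------------------------------

#' Default run configuration
#'
#' Nested configuration covering data generation, preprocessing, model and
#' training settings, serializable to YAML. Unknown keys are rejected when
#' reading, so typos fail loudly.
#'
#' @return a nested `run_config` list.
#' @export
default_run_config <- function() {
  structure(list(
    schema_version = 1L,
    data = list(n = 64L, image_size = 64L, noise_sigma = 0.04,
                n_nodules_min = 0L, n_nodules_max = 5L,
                split = c(0.8, 0.1, 0.1), seed = 1L),
    preprocessing = list(median_window = 3L, diffusion_iterations = 10L,
                         kappa = 30, gamma = 0.1, kmeans_k = 2L,
                         opening_radius = 2L, dilation_radius = 5L,
                         min_area_fraction = 0.005, border_margin = 2L),
    model = list(architecture = "fpn_la", activation = "GELU",
                 pyramid_width = 64L, seed = 1L),
    training = list(epochs = 15L, batch_size = 8L, learning_rate = 1e-5,
                    weight_decay = 1e-4, w_bce = 0.5, w_dice = 0.5,
                    smooth = 1.0, threshold = 0.5, seed = 1L)
  ), class = "run_config")
}

check_config_keys <- function(value, template, path = "") {
  extra <- setdiff(names(value), names(template))
  if (length(extra)) {
    stop("unknown configuration key(s): ",
         paste0(path, extra, collapse = ", "))
  }
  for (nm in names(value)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
      check_config_keys(value[[nm]], template[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

#' Read / write a run configuration
#'
#' @param path YAML file.
#' @return `read_run_config` the merged `run_config` (file values override
#'   defaults); `write_run_config` the path, invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- default_run_config()
  check_config_keys(raw, base)
  merge_into <- function(base, value) {
    for (nm in names(value)) {
      base[[nm]] <- if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
        merge_into(base[[nm]], value[[nm]])
      } else value[[nm]]
    }
    base
  }
  structure(merge_into(unclass(base), raw), class = "run_config")
}

#' @rdname read_run_config
#' @param config a `run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
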