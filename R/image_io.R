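#' @useDynLib fuccistage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Three-plane fluorescence image
#'
#' Container for one registered field of view: the Fucci2 red reporter plane,
#' the Fucci2 green reporter plane and the DAPI plane (stored on the blue
#' channel of RGB files). Planes are numeric matrices indexed `[row, col]`.
#'
#' @param red,green,blue Numeric matrices of identical dimensions with
#'   intensities in `[0, 2^bit_depth - 1]`.
#' @param bit_depth Bits per channel of the source data (8 or 16).
#' @param image_id,experiment_id Identifiers carried through the pipeline.
#' @return An object of class `fluorescence_image` with fields `red`,
#'   `green`, `blue`, `bit_depth`, `image_id`, `experiment_id`.
#' @export
fluorescence_image <- function(red, green, blue, bit_depth = 8L,
                               image_id = "", experiment_id = "") {
  if (!is.matrix(red) || !is.matrix(green) || !is.matrix(blue))
    stop("planes must be matrices")
  if (!identical(dim(red), dim(green)) || !identical(dim(red), dim(blue)))
    stop("all three planes must share identical dimensions")
  maxv <- 2^bit_depth - 1
  for (pl in list(red, green, blue)) {
    rng <- range(pl)
    if (rng[1] < 0) stop("negative intensities are not allowed")
    if (rng[2] > maxv)
      stop(sprintf("intensity %g exceeds bit depth %d maximum %g",
                   rng[2], bit_depth, maxv))
  }
  structure(
    list(red = red, green = green, blue = blue,
         bit_depth = as.integer(bit_depth),
         image_id = as.character(image_id),
         experiment_id = as.character(experiment_id)),
    class = "fluorescence_image")
}

#' @export
print.fluorescence_image <- function(x, ...) {
  cat(sprintf("<fluorescence_image %s [%s]: %d x %d px, %d-bit>\n",
              x$image_id, x$experiment_id, nrow(x$red), ncol(x$red),
              x$bit_depth))
  invisible(x)
}

#' @export
dim.fluorescence_image <- function(x) dim(x$red)

#' Single-nucleus binary mask
#'
#' A sparse representation of one nucleus mask b_k: the linear (column-major)
#' pixel indices that belong to the nucleus, plus the full image dimensions.
#'
#' @param pixels Integer vector of linear indices into a `dim[1] x dim[2]`
#'   matrix; at least one pixel.
#' @param dim Integer vector `c(height, width)` of the source image.
#' @param nucleus_id Integer id (>= 1).
#' @return An object of class `nucleus_mask` with fields `pixels`, `dim`,
#'   `nucleus_id` and `bbox` (`row_min, col_min, row_max, col_max`,
#'   0-based half-open).
#' @export
nucleus_mask <- function(pixels, dim, nucleus_id = 1L) {
  dim <- as.integer(dim)
  pixels <- sort(unique(as.integer(pixels)))
  if (length(pixels) < 1L) stop("a nucleus mask needs at least one pixel")
  if (pixels[1] < 1L || pixels[length(pixels)] > prod(dim))
    stop("pixel index out of bounds")
  rows <- (pixels - 1L) %% dim[1] + 1L
  cols <- (pixels - 1L) %/% dim[1] + 1L
  structure(
    list(pixels = pixels, dim = as.integer(dim),
         nucleus_id = as.integer(nucleus_id),
         bbox = c(row_min = min(rows) - 1L, col_min = min(cols) - 1L,
                  row_max = max(rows), col_max = max(cols))),
    class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("<nucleus_mask id=%d: %d px in %d x %d image>\n",
              x$nucleus_id, length(x$pixels), x$dim[1], x$dim[2]))
  invisible(x)
}

#' Densify a nucleus mask to a 0/1 matrix
#' @param mask A [nucleus_mask()].
#' @return Integer matrix of the source image dimensions.
#' @export
mask_matrix <- function(mask) {
  m <- matrix(0L, mask$dim[1], mask$dim[2])
  m[mask$pixels] <- 1L
  m
}

## ---- RGB image files -------------------------------------------------------

#' Read a 3-channel fluorescence image
#'
#' Reads an RGB image with the Fucci2 red reporter on channel R, the green
#' reporter on channel G and DAPI on channel B. PNG (8- or 16-bit) and ASCII
#' PPM (`P3`) files are supported; TIFF is not available in this toolchain.
#'
#' @param path Path to a `.png` or `.ppm` file with at least 3 channels.
#' @param image_id,experiment_id Identifiers to attach; `image_id` defaults
#'   to the file name without extension.
#' @return A [fluorescence_image()].
#' @export
read_rgb_image <- function(path, image_id = NULL, experiment_id = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(image_id)) image_id <- sub("\\.[^.]+$", "", basename(path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path, info = TRUE)
    info <- attr(a, "info")
    depth <- as.integer(info$bit.depth)
    if (length(dim(a)) < 3L || dim(a)[3] < 3L)
      stop("fewer than 3 channels in ", path)
    maxv <- 2^depth - 1
    fluorescence_image(round(a[, , 1] * maxv), round(a[, , 2] * maxv),
                       round(a[, , 3] * maxv), bit_depth = depth,
                       image_id = image_id, experiment_id = experiment_id)
  } else if (grepl("\\.ppm$", path, ignore.case = TRUE)) {
    p <- read_pnm(path)
    if (p$channels < 3L) stop("fewer than 3 channels in ", path)
    depth <- if (p$maxval > 255) 16L else 8L
    fluorescence_image(p$planes[[1]], p$planes[[2]], p$planes[[3]],
                       bit_depth = depth, image_id = image_id,
                       experiment_id = experiment_id)
  } else stop("unsupported image format (use .png or .ppm): ", path)
}

#' Write a 3-channel fluorescence image
#'
#' 8-bit images are written as PNG; 16-bit images as ASCII PPM (`P3`),
#' since the PNG writer available here is 8-bit only.
#'
#' @param image A [fluorescence_image()].
#' @param path Output path; extension selects the format.
#' @export
write_rgb_image <- function(image, path) {
  stopifnot(inherits(image, "fluorescence_image"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (image$bit_depth != 8L)
      stop("PNG output supports 8-bit only; use .ppm for 16-bit")
    a <- array(0, dim = c(dim(image$red), 3L))
    a[, , 1] <- image$red / 255
    a[, , 2] <- image$green / 255
    a[, , 3] <- image$blue / 255
    png::writePNG(a, path)
  } else if (grepl("\\.ppm$", path, ignore.case = TRUE)) {
    write_pnm(list(image$red, image$green, image$blue),
              2^image$bit_depth - 1, path, magic = "P3")
  } else stop("unsupported image format (use .png or .ppm): ", path)
  invisible(path)
}

## ---- labeled masks ---------------------------------------------------------

#' Read a labeled segmentation mask
#'
#' A labeled mask image assigns 0 to background and an integer id k >= 1 to
#' every pixel of nucleus k. ASCII PGM (`P2`, 16-bit capable) and 8/16-bit
#' grayscale PNG are supported. One id split across several 8-connected
#' components is accepted with a warning (real segmenters occasionally emit
#' such masks).
#'
#' @param path Path to a `.pgm` or `.png` labeled mask.
#' @return List of [nucleus_mask()] objects, one per distinct positive id,
#'   in increasing id order.
#' @export
read_label_mask <- function(path) {
  lab <- read_label_matrix(path)
  label_matrix_to_masks(lab)
}

read_label_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    p <- read_pnm(path)
    if (p$channels != 1L) stop("label masks must be single-channel")
    p$planes[[1]]
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path, info = TRUE)
    depth <- attr(a, "info")$bit.depth
    if (length(dim(a)) == 3L) a <- a[, , 1]
    round(a * (2^depth - 1))
  } else stop("unsupported mask format (use .pgm or .png): ", path)
}

#' Convert a labeled matrix to per-nucleus masks
#' @param lab Integer matrix, 0 = background, k >= 1 = nucleus k.
#' @return List of [nucleus_mask()].
#' @export
label_matrix_to_masks <- function(lab) {
  if (any(lab < 0)) stop("negative labels are not allowed")
  if (any(abs(lab - round(lab)) > 1e-9)) stop("non-integer label values")
  ids <- sort(unique(lab[lab > 0]))
  masks <- lapply(ids, function(id) {
    m <- nucleus_mask(which(lab == id), dim(lab), nucleus_id = id)
    if (n_components(m) > 1L)
      warning(sprintf("label %d is split into multiple connected components",
                      as.integer(id)))
    m
  })
  masks
}

#' Convert per-nucleus masks to one labeled matrix
#' @param masks List of [nucleus_mask()] sharing dimensions.
#' @param dim Image dimensions, defaulting to the first mask's.
#' @return Integer label matrix.
#' @export
masks_to_label_matrix <- function(masks, dim = NULL) {
  if (is.null(dim)) {
    if (length(masks) == 0L) stop("dim required for an empty mask list")
    dim <- masks[[1]]$dim
  }
  lab <- matrix(0L, dim[1], dim[2])
  for (m in masks) lab[m$pixels] <- m$nucleus_id
  lab
}

#' Write a labeled segmentation mask (ASCII PGM, 16-bit range)
#' @param masks List of [nucleus_mask()] or an integer label matrix.
#' @param path Output `.pgm` path.
#' @param dim Image dimensions when `masks` is an empty list.
#' @export
write_label_mask <- function(masks, path, dim = NULL) {
  lab <- if (is.matrix(masks)) masks else masks_to_label_matrix(masks, dim)
  if (max(lab) > 65535) stop("label ids exceed 16-bit range")
  write_pnm(list(lab), 65535L, path, magic = "P2")
  invisible(path)
}

## ---- NetPBM (ASCII) --------------------------------------------------------

read_pnm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  magic <- toks[1]
  if (!magic %in% c("P2", "P3")) stop("unsupported PNM magic: ", magic)
  channels <- if (magic == "P3") 3L else 1L
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxval <- as.integer(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h * channels) stop("truncated PNM file: ", path)
  planes <- vector("list", channels)
  for (ch in seq_len(channels)) {
    # pixel order: row-major, channels interleaved
    v <- vals[seq(ch, length(vals), by = channels)]
    planes[[ch]] <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
  }
  list(planes = planes, maxval = maxval, channels = channels)
}

write_pnm <- function(planes, maxval, path, magic = c("P2", "P3")) {
  magic <- match.arg(magic)
  h <- nrow(planes[[1]]); w <- ncol(planes[[1]])
  vals <- matrix(0L, length(planes), h * w)
  for (ch in seq_along(planes)) {
    m <- round(t(planes[[ch]]))  # row-major order
    vals[ch, ] <- as.integer(pmin(pmax(m, 0), maxval))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(magic, paste(w, h), as.character(maxval)), con)
  writeLines(paste(apply(vals, 2, paste, collapse = " "), collapse = "\n"),
             con)
  invisible(path)
}

## ---- manifests and feature tables -----------------------------------------

#' Read a dataset manifest
#'
#' CSV with columns `image_path`, `mask_path` (may be empty) and
#' `experiment_id`, grouping images into acquisition experiments. Relative
#' paths are resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @param check_paths Verify that every referenced file exists (default TRUE).
#' @return A data.frame with absolute `image_path`/`mask_path` columns.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "mask_path", "experiment_id")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(is.na(p) | p == "", NA_character_,
                                ifelse(grepl("^/", p), p,
                                       file.path(base, p)))
  df$image_path <- resolve(df$image_path)
  df$mask_path <- resolve(df$mask_path)
  if (check_paths) {
    for (p in c(df$image_path, df$mask_path[!is.na(df$mask_path)]))
      if (!file.exists(p)) stop("manifest references a missing file: ", p)
  }
  df$experiment_id <- as.character(df$experiment_id)
  df
}

#' @rdname read_manifest
#' @param manifest Data.frame with the manifest columns.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[, c("image_path", "mask_path", "experiment_id")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

feature_table_columns <- c(
  "image_id", "experiment_id", "nucleus_id", "area", "total_dapi",
  "total_red", "total_green", "mean_red", "mean_green",
  "norm_red", "norm_green")

#' Write / read a per-nucleus feature table
#'
#' Stable-order CSV with one row per nucleus: identifiers, area A, total
#' intensities TI (DAPI/red/green), mean and unit-normalized Fucci colors,
#' plus any label columns present. Numeric round trip is lossless to well
#' below 1e-9 relative.
#'
#' @param records Data.frame of per-nucleus rows.
#' @param path Output CSV path.
#' @export
write_feature_table <- function(records, path) {
  core <- intersect(feature_table_columns, names(records))
  extra <- setdiff(names(records), feature_table_columns)
  df <- records[, c(core, extra), drop = FALSE]
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  for (cn in names(df)[num]) df[[cn]] <- sprintf("%.12g", df[[cn]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(image_id = "character",
                                 experiment_id = "character"))
}
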