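#' Baseline segmenter configuration
#'
#' @param min_area Minimum nucleus area in pixels (components below are
#'   discarded as debris). Default 50.
#' @param smoothing_sigma Gaussian smoothing sigma in pixels applied to the
#'   DAPI plane before thresholding. Default 2.
#' @param threshold_method Only `"otsu"` is implemented.
#' @param split_touching Split touching nuclei with a distance-transform
#'   watershed. Default FALSE: the bundled synthetic data places nuclei
#'   without contact, and splitting is best-effort on real clumps.
#' @return A list of class `segmenter_config`.
#' @export
segmenter_config <- function(min_area = 50L, smoothing_sigma = 2,
                             threshold_method = "otsu",
                             split_touching = FALSE) {
  stopifnot(min_area >= 1, smoothing_sigma >= 0,
            threshold_method == "otsu")
  structure(list(min_area = as.integer(min_area),
                 smoothing_sigma = smoothing_sigma,
                 threshold_method = threshold_method,
                 split_touching = isTRUE(split_touching)),
            class = "segmenter_config")
}

#' Classical baseline nucleus segmentation
#'
#' Gaussian smoothing, global Otsu threshold, 8-connected component
#' labeling, optional distance-transform watershed to split touching
#' nuclei, and a minimum-area filter. This is a stand-in for external deep
#' segmenters: any backend that yields disjoint per-nucleus masks can be
#' plugged in downstream via labeled mask files.
#'
#' @param dapi_plane Numeric matrix of DAPI intensities.
#' @param cfg A [segmenter_config()].
#' @return List of disjoint [nucleus_mask()] (possibly empty), ids 1..n.
#' @export
segment_baseline <- function(dapi_plane, cfg = segmenter_config()) {
  stopifnot(is.matrix(dapi_plane), length(dapi_plane) > 0)
  sm <- if (cfg$smoothing_sigma > 0)
    gaussian_blur(dapi_plane, cfg$smoothing_sigma) else dapi_plane
  thr <- otsu_threshold(sm)
  binary <- sm > thr
  if (!any(binary)) return(list())
  lab <- if (cfg$split_touching) watershed_split(binary)
         else label_components(binary)
  ids <- sort(unique(lab[lab > 0]))
  masks <- list()
  k <- 0L
  for (id in ids) {
    px <- which(lab == id)
    if (length(px) < cfg$min_area) next
    k <- k + 1L
    masks[[k]] <- nucleus_mask(px, dim(dapi_plane), nucleus_id = k)
  }
  masks
}

#' Drop nuclei touching the image border
#'
#' Border nuclei carry incomplete information (partial area and intensity)
#' and are removed before any feature extraction.
#'
#' @param masks List of [nucleus_mask()].
#' @param height,width Image dimensions in pixels.
#' @return The masks whose pixels all lie strictly inside the border,
#'   original order preserved.
#' @export
remove_border_nuclei <- function(masks, height, width) {
  keep <- vapply(masks, function(m) {
    bb <- m$bbox
    bb["row_min"] > 0L && bb["col_min"] > 0L &&
      bb["row_max"] < height && bb["col_max"] < width
  }, logical(1))
  masks[keep]
}

#' Intersection-over-union of two masks
#' @param a,b [nucleus_mask()] objects with identical dimensions.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  if (!identical(a$dim, b$dim)) stop("masks have different dimensions")
  inter <- length(intersect(a$pixels, b$pixels))
  uni <- length(a$pixels) + length(b$pixels) - inter
  if (uni == 0L) stop("both masks are empty")
  inter / uni
}

## ---- low-level image ops ---------------------------------------------------

# Separable Gaussian blur with replicated edges.
gaussian_blur <- function(m, sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (d in (-r):r) {  # rows
    idx <- pmin(pmax(seq_len(h) + d, 1L), h)
    out <- out + k[d + r + 1] * m[idx, , drop = FALSE]
  }
  m2 <- matrix(0, h, w)
  for (d in (-r):r) {  # cols
    idx <- pmin(pmax(seq_len(w) + d, 1L), w)
    m2 <- m2 + k[d + r + 1] * out[, idx, drop = FALSE]
  }
  m2
}

# Otsu's threshold on a 256-bin histogram between min and max.
otsu_threshold <- function(m) {
  v <- as.numeric(m)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(hi)  # flat image: nothing above threshold
  nb <- 256L
  h <- tabulate(pmin(floor((v - lo) / (hi - lo) * nb) + 1L, nb), nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- lo + (seq_len(nb) - 0.5) * (hi - lo) / nb
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  denom <- omega * (1 - omega)
  sb <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, Inf)
  lo + which.max(sb) * (hi - lo) / nb
}

# 8-connected component labeling by batched flood fill.
label_components <- function(binary) {
  h <- nrow(binary); w <- ncol(binary)
  lab <- matrix(0L, h, w)
  todo <- binary > 0
  seeds <- which(todo)
  nid <- 0L
  for (s in seeds) {
    if (!todo[s]) next
    nid <- nid + 1L
    frontier <- s
    todo[s] <- FALSE
    lab[s] <- nid
    while (length(frontier)) {
      nb <- neighbors8(frontier, h, w)
      nb <- nb[todo[nb]]
      if (!length(nb)) break
      nb <- unique(nb)
      todo[nb] <- FALSE
      lab[nb] <- nid
      frontier <- nb
    }
  }
  lab
}

# All valid 8-neighbors of a set of linear indices (with duplicates).
neighbors8 <- function(idx, h, w) {
  row <- (idx - 1L) %% h + 1L
  col <- (idx - 1L) %/% h + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    r2 <- row + dr; c2 <- col + dc
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    if (any(ok)) out <- c(out, (c2[ok] - 1L) * h + r2[ok])
  }
  out
}

n_components <- function(mask) {
  bb <- mask$bbox
  sub <- mask_matrix(mask)[(bb["row_min"] + 1L):bb["row_max"],
                           (bb["col_min"] + 1L):bb["col_max"], drop = FALSE]
  max(label_components(sub))
}

# Two-pass chamfer (3-4) distance transform of a binary foreground.
chamfer_distance <- function(binary) {
  h <- nrow(binary); w <- ncol(binary)
  big <- 3 * (h + w)
  d <- matrix(0, h, w)
  d[binary] <- big
  for (j in seq_len(w)) for (i in seq_len(h)) {   # forward
    if (d[i, j] == 0) next
    v <- d[i, j]
    if (i > 1) v <- min(v, d[i - 1, j] + 3)
    if (j > 1) v <- min(v, d[i, j - 1] + 3)
    if (i > 1 && j > 1) v <- min(v, d[i - 1, j - 1] + 4)
    if (i < h && j > 1) v <- min(v, d[i + 1, j - 1] + 4)
    d[i, j] <- v
  }
  for (j in rev(seq_len(w))) for (i in rev(seq_len(h))) {  # backward
    if (d[i, j] == 0) next
    v <- d[i, j]
    if (i < h) v <- min(v, d[i + 1, j] + 3)
    if (j < w) v <- min(v, d[i, j + 1] + 3)
    if (i < h && j < w) v <- min(v, d[i + 1, j + 1] + 4)
    if (i > 1 && j < w) v <- min(v, d[i - 1, j + 1] + 4)
    d[i, j] <- v
  }
  d / 3
}

# Marker-based watershed on the distance transform: seeds are merged local
# maxima; remaining foreground is attached to the highest labeled neighbor
# in decreasing-distance order.
watershed_split <- function(binary) {
  h <- nrow(binary); w <- ncol(binary)
  d <- chamfer_distance(binary)
  ds <- gaussian_blur(d, 1)
  ds[!binary] <- 0
  # local maxima in a 5x5 window
  mx <- ds
  for (dr in -2:2) for (dc in -2:2) {
    if (dr == 0L && dc == 0L) next
    ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
    ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
    mx <- pmax(mx, ds[ri, ci])
  }
  seeds <- binary & ds >= mx & ds > 1
  lab <- label_components(seeds)
  if (max(lab) == 0L) return(label_components(binary))
  rest <- which(binary & lab == 0L)
  rest <- rest[order(-d[rest])]
  repeat {
    unassigned <- integer(0)
    assigned_any <- FALSE
    for (p in rest) {
      nb <- neighbors8(p, h, w)
      nl <- lab[nb]
      nl <- nl[nl > 0L]
      if (length(nl)) {
        best <- nb[lab[nb] > 0L][which.max(d[nb[lab[nb] > 0L]])]
        lab[p] <- lab[best]
        assigned_any <- TRUE
      } else unassigned <- c(unassigned, p)
    }
    if (!length(unassigned)) break
    if (!assigned_any) {
      # isolated regions without a seed keep their own component id
      extra <- label_components(matrix(seq_len(h * w) %in% unassigned, h, w))
      lab[unassigned] <- max(lab) + extra[unassigned]
      break
    }
    rest <- unassigned
  }
  lab
}
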