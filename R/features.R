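#' Nucleus area (pixel count)
#' @param mask A [nucleus_mask()].
#' @return Number of set pixels.
#' @export
compute_area <- function(mask) {
  stopifnot(inherits(mask, "nucleus_mask"))
  length(mask$pixels)
}

#' Total (integrated) intensity of a nucleus on one plane
#'
#' Sum over the masked pixels of the plane, i.e. sum_ij b_k(i,j) P(i,j).
#' Accumulation is in double precision whatever the input storage type.
#'
#' @param mask A [nucleus_mask()].
#' @param plane Numeric matrix with the mask's dimensions.
#' @return The integrated intensity (intensity x pixels).
#' @export
compute_total_intensity <- function(mask, plane) {
  stopifnot(inherits(mask, "nucleus_mask"), is.matrix(plane))
  if (!identical(dim(plane), as.integer(mask$dim)))
    stop("plane dimensions do not match the mask")
  sum(as.numeric(plane[mask$pixels]))
}

#' Mean Fucci intensities of a nucleus
#' @param total_red,total_green Integrated Fucci intensities.
#' @param area Nucleus area in pixels (>= 1).
#' @return Named vector `c(mean_red, mean_green)`.
#' @export
compute_mean_intensities <- function(total_red, total_green, area) {
  if (area < 1) stop("area must be >= 1")
  c(mean_red = total_red / area, mean_green = total_green / area)
}

#' Unit-normalized Fucci color
#'
#' Projects the mean-intensity vector onto the unit quarter-circle so the
#' red/green hue is captured independently of overall brightness: each mean
#' is divided by sqrt(mean_red^2 + mean_green^2).
#'
#' @param mean_red,mean_green Mean channel intensities (nonnegative).
#' @return Named vector `c(norm_red, norm_green)`; both `NA` (undefined)
#'   when both means are zero — such colorless nuclei are excluded as dark
#'   downstream anyway.
#' @export
normalize_color <- function(mean_red, mean_green) {
  nrm <- sqrt(mean_red^2 + mean_green^2)
  if (nrm == 0)
    return(c(norm_red = NA_real_, norm_green = NA_real_))
  c(norm_red = mean_red / nrm, norm_green = mean_green / nrm)
}

#' Extract all per-nucleus features of one image
#'
#' Computes, for every mask, the area, the integrated DAPI/red/green
#' intensities, the mean Fucci intensities and the unit-normalized color.
#' The image should already be background-subtracted (see
#' [subtract_background()]); set `raw = TRUE` only for ablations.
#'
#' @param image A [fluorescence_image()], or `NULL` planes allowed in
#'   DAPI-only deployment via `dapi_only = TRUE`.
#' @param masks List of disjoint [nucleus_mask()].
#' @param dapi_only When TRUE only `area` and `total_dapi` are populated;
#'   Fucci columns are `NA` (the staging deployment path).
#' @return Data.frame with one row per mask ordered by `nucleus_id`, columns
#'   `image_id, experiment_id, nucleus_id, area, total_dapi, total_red,
#'   total_green, mean_red, mean_green, norm_red, norm_green`.
#' @export
extract_features <- function(image, masks, dapi_only = FALSE) {
  stopifnot(inherits(image, "fluorescence_image"))
  masks <- masks[order(vapply(masks, `[[`, integer(1), "nucleus_id"))]
  n <- length(masks)
  df <- data.frame(
    image_id = rep(image$image_id, n),
    experiment_id = rep(image$experiment_id, n),
    nucleus_id = vapply(masks, `[[`, integer(1), "nucleus_id"),
    area = vapply(masks, compute_area, numeric(1)),
    total_dapi = vapply(masks, compute_total_intensity, numeric(1),
                        plane = image$blue),
    stringsAsFactors = FALSE)
  if (dapi_only) {
    df$total_red <- df$total_green <- NA_real_
    df$mean_red <- df$mean_green <- NA_real_
    df$norm_red <- df$norm_green <- NA_real_
  } else {
    df$total_red <- vapply(masks, compute_total_intensity, numeric(1),
                           plane = image$red)
    df$total_green <- vapply(masks, compute_total_intensity, numeric(1),
                             plane = image$green)
    df$mean_red <- df$total_red / df$area
    df$mean_green <- df$total_green / df$area
    nrm <- sqrt(df$mean_red^2 + df$mean_green^2)
    df$norm_red <- ifelse(nrm > 0, df$mean_red / nrm, NA_real_)
    df$norm_green <- ifelse(nrm > 0, df$mean_green / nrm, NA_real_)
  }
  df[feature_table_columns]
}
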