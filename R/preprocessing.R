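#' Estimate per-channel mean background intensity
#'
#' Background is every pixel outside the union of the supplied nucleus
#' masks; the estimate is the arithmetic mean of those pixels per channel.
#'
#' @param image A [fluorescence_image()].
#' @param masks List of [nucleus_mask()] for this image.
#' @return A list of class `background_estimate` with `mean_red`,
#'   `mean_green`, `mean_blue`.
#' @export
estimate_background_mean <- function(image, masks) {
  stopifnot(inherits(image, "fluorescence_image"))
  inside <- unique(unlist(lapply(masks, `[[`, "pixels")))
  n <- prod(dim(image$red))
  if (length(inside) >= n)
    stop("masks cover every pixel; no background to estimate")
  keep <- rep(TRUE, n)
  keep[inside] <- FALSE
  structure(list(mean_red = mean(image$red[keep]),
                 mean_green = mean(image$green[keep]),
                 mean_blue = mean(image$blue[keep])),
            class = "background_estimate")
}

#' Subtract a background estimate from every pixel
#'
#' Each channel's mean background is subtracted from all its pixels;
#' results below zero are clamped to zero so downstream intensity sums stay
#' nonnegative. Output planes are floating point (not re-quantized).
#'
#' @param image A [fluorescence_image()].
#' @param bg A `background_estimate` from [estimate_background_mean()].
#' @return A [fluorescence_image()] of the same dimensions.
#' @export
subtract_background <- function(image, bg) {
  stopifnot(inherits(image, "fluorescence_image"),
            inherits(bg, "background_estimate"))
  if (!all(is.finite(c(bg$mean_red, bg$mean_green, bg$mean_blue))))
    stop("background means must be finite")
  out <- image
  out$red <- pmax(image$red - bg$mean_red, 0)
  out$green <- pmax(image$green - bg$mean_green, 0)
  out$blue <- pmax(image$blue - bg$mean_blue, 0)
  out
}
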