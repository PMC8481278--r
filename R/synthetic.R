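#' Synthetic Fucci2 + DAPI dataset configuration
#'
#' The generator paints elliptical nuclei on a dark background, three
#' planes per field: Fucci2 red (high in G1), Fucci2 green (high in S/G2)
#' and DAPI. Defaults encode the biology the pipeline assumes: 64.5% of
#' labelable nuclei in G1; S/G2 nuclei 1.5x larger in area and 1.8x
#' brighter in integrated DAPI (S-phase nuclei sit between 2N and 4N, so
#' the integrated-intensity ratio is deliberately below 2 and the class
#' histograms overlap); a small share of transition nuclei with near-equal
#' reporter channels and of dark nuclei with both channels below the
#' darkness threshold; additive background plus Gaussian noise.
#'
#' @param width,height Image size in pixels (default 256 x 256).
#' @param n_nuclei Nuclei per image: a count or a `c(min, max)` range
#'   (default 28-32, about 30 per field).
#' @param frac_g1 Fraction of G1 among labelable (G1 + S/G2) nuclei
#'   (default 0.645).
#' @param frac_transition,frac_dark Fractions of all nuclei in the
#'   transition and dark states (defaults 0.04 each).
#' @param area_mean_g1,area_sd_g1 G1 area distribution in pixels
#'   (default 250 +/- 25).
#' @param area_multiplier_sg2 Multiplier on the G1 area distribution for
#'   S/G2 (default 1.5; scales mean and sd).
#' @param dapi_pixel_mean_g1,dapi_pixel_sd_g1 Per-pixel DAPI level of a G1
#'   nucleus, 8-bit units (default 90 +/- 6 across nuclei; constant within
#'   a nucleus).
#' @param dapi_total_multiplier_sg2 Ratio of integrated DAPI intensity
#'   S/G2 : G1 (default 1.8); the per-pixel S/G2 level is this ratio
#'   divided by the area multiplier.
#' @param red_g1,green_g1 Mean/sd of the Fucci reporter levels of a G1
#'   nucleus (red high, green low); S/G2 uses the same pair swapped.
#' @param transition_level Mean/sd of the common reporter level of a
#'   transition nucleus; its green/red ratio is drawn uniformly in
#'   `(0.92, 1.08)`, inside the exclusion band.
#' @param dark_level Mean/sd of both reporter levels of a dark nucleus
#'   (clamped below 35 so both means stay under the darkness threshold).
#' @param background_offset Additive background, all channels (default 10).
#' @param noise_sd Gaussian pixel noise sd (default 5).
#' @param gain_jitter Half-width of the per-experiment uniform gain factor
#'   applied to the DAPI plane (default 0 = identical acquisition gain;
#'   0.3 emulates +/-30% batch-to-batch variation).
#' @param bit_depth Bits per channel (default 8).
#' @param min_gap Minimum Chebyshev gap between nuclei and to the border.
#' @param seed Master seed; every random draw descends from it.
#' @param preset `"paperlike"` (defaults above), `"separable"` (wide class
#'   separation, no transition/dark nuclei) or `"overlapping"` (weaker
#'   DAPI contrast, more noise).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(width = 256L, height = 256L,
                             n_nuclei = c(28L, 32L),
                             frac_g1 = 0.645, frac_transition = 0.04,
                             frac_dark = 0.04,
                             area_mean_g1 = 250, area_sd_g1 = 25,
                             area_multiplier_sg2 = 1.5,
                             dapi_pixel_mean_g1 = 90, dapi_pixel_sd_g1 = 6,
                             dapi_total_multiplier_sg2 = 1.8,
                             red_g1 = c(mean = 150, sd = 20),
                             green_g1 = c(mean = 25, sd = 8),
                             transition_level = c(mean = 90, sd = 15),
                             dark_level = c(mean = 15, sd = 5),
                             background_offset = 10, noise_sd = 5,
                             gain_jitter = 0, bit_depth = 8L,
                             min_gap = 3L, seed = 0L,
                             preset = c("paperlike", "separable",
                                        "overlapping")) {
  preset <- match.arg(preset)
  cfg <- as.list(environment())
  cfg$preset <- preset
  if (preset == "separable") {
    # wide separation must survive the 1-sigma area exclusion: a large
    # area multiplier would differentially exclude S/G2, so separation is
    # carried by the DAPI contrast while areas stay nearly unimodal
    cfg$area_multiplier_sg2 <- 1.1
    cfg$dapi_total_multiplier_sg2 <- 2.5
    cfg$area_sd_g1 <- 15
    cfg$dapi_pixel_sd_g1 <- 4
    cfg$frac_transition <- 0
    cfg$frac_dark <- 0
    cfg$noise_sd <- 2
  } else if (preset == "overlapping") {
    cfg$dapi_total_multiplier_sg2 <- 1.4
    cfg$noise_sd <- 8
  }
  stopifnot(cfg$frac_g1 >= 0, cfg$frac_g1 <= 1,
            cfg$frac_transition + cfg$frac_dark <= 1,
            cfg$area_multiplier_sg2 > 0,
            cfg$dapi_total_multiplier_sg2 > 0,
            cfg$seed < 2^31)
  structure(cfg, class = "synthetic_config")
}

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) %% 65536 * 9176 + k * 7919 + 13) %%
               2147483647)
}

rnorm_pos <- function(n, mean, sd, lower = 0) pmax(stats::rnorm(n, mean, sd),
                                                   lower)

#' Draw one nucleus (geometry and radiometry) for a given state
#'
#' @param state One of `"G1"`, `"S_G2"`, `"transition"`, `"dark"`.
#' @param cfg A [synthetic_config()].
#' @return List with `state`, `area` (target, pixels), `axis_ratio`,
#'   `theta`, `dapi_level`, `red_level`, `green_level`.
#' @export
sample_nucleus <- function(state, cfg) {
  am <- cfg$area_mean_g1; asd <- cfg$area_sd_g1
  dm <- cfg$dapi_pixel_mean_g1; dsd <- cfg$dapi_pixel_sd_g1
  sg2_pix_mult <- cfg$dapi_total_multiplier_sg2 / cfg$area_multiplier_sg2
  if (state == "S_G2") {
    am <- am * cfg$area_multiplier_sg2
    asd <- asd * cfg$area_multiplier_sg2
    dm <- dm * sg2_pix_mult
    dsd <- dsd * sg2_pix_mult
  } else if (state == "transition") {
    # G1/S boundary: intermediate size and DNA content
    am <- am * (1 + (cfg$area_multiplier_sg2 - 1) / 2)
    dm <- dm * (1 + (sg2_pix_mult - 1) / 2)
  } else if (state == "dark") {
    # Fucci-silent nucleus with an ordinary G1-like morphology
    am <- am; dm <- dm
  }
  area <- max(rnorm_pos(1, am, asd), 30)
  if (state == "G1") {
    red <- rnorm_pos(1, cfg$red_g1["mean"], cfg$red_g1["sd"])
    green <- rnorm_pos(1, cfg$green_g1["mean"], cfg$green_g1["sd"])
  } else if (state == "S_G2") {
    red <- rnorm_pos(1, cfg$green_g1["mean"], cfg$green_g1["sd"])
    green <- rnorm_pos(1, cfg$red_g1["mean"], cfg$red_g1["sd"])
  } else if (state == "transition") {
    red <- rnorm_pos(1, cfg$transition_level["mean"],
                     cfg$transition_level["sd"], lower = 45)
    green <- red * stats::runif(1, 0.92, 1.08)
  } else {
    red <- min(rnorm_pos(1, cfg$dark_level["mean"], cfg$dark_level["sd"]), 35)
    green <- min(rnorm_pos(1, cfg$dark_level["mean"], cfg$dark_level["sd"]),
                 35)
  }
  list(state = state, area = area,
       axis_ratio = stats::runif(1, 1, 1.5),
       theta = stats::runif(1, 0, pi),
       dapi_level = rnorm_pos(1, dm, dsd, lower = 20),
       red_level = red, green_level = green)
}

sample_states <- function(n, cfg) {
  p_lab <- 1 - cfg$frac_transition - cfg$frac_dark
  probs <- c(G1 = p_lab * cfg$frac_g1, S_G2 = p_lab * (1 - cfg$frac_g1),
             transition = cfg$frac_transition, dark = cfg$frac_dark)
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# Rasterize an ellipse of the given target area at center (r0, c0).
ellipse_pixels <- function(r0, c0, area, axis_ratio, theta, h, w) {
  b <- sqrt(area / (pi * axis_ratio))   # minor semi-axis
  a <- axis_ratio * b
  ext <- ceiling(a) + 1L
  rows <- max(1L, floor(r0 - ext)):min(h, ceiling(r0 + ext))
  cols <- max(1L, floor(c0 - ext)):min(w, ceiling(c0 + ext))
  rg <- rep(rows, times = length(cols))
  cg <- rep(cols, each = length(rows))
  dr <- rg - r0; dc <- cg - c0
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  (cg[inside] - 1L) * h + rg[inside]
}

#' Render one synthetic field of view
#'
#' Places the drawn nuclei without overlap (rejection sampling with a
#' retry cap), paints the three planes, adds background and Gaussian
#' noise, quantizes to the configured bit depth and returns the image, the
#' labeled mask and the ground-truth bookkeeping. Ground-truth integrated
#' intensities are computed from the quantized noise-free planes, so in
#' the noiseless limit they agree exactly with the feature extractor.
#'
#' @param nuclei List of draws from [sample_nucleus()].
#' @param cfg A [synthetic_config()].
#' @param image_id,experiment_id Identifiers for the rendered image.
#' @param dapi_gain Multiplicative gain on the DAPI plane (default 1).
#' @return List with `image` ([fluorescence_image()]), `label_matrix`,
#'   `masks` and `truth` (data.frame, one row per rendered nucleus).
#' @export
render_image <- function(nuclei, cfg, image_id = "img",
                         experiment_id = "exp", dapi_gain = 1) {
  h <- cfg$height; w <- cfg$width
  occupied <- matrix(FALSE, h, w)
  lab <- matrix(0L, h, w)
  red0 <- matrix(0, h, w); green0 <- matrix(0, h, w); blue0 <- matrix(0, h, w)
  margin <- cfg$min_gap + 1
  gap_off <- expand.grid(dr = -cfg$min_gap:cfg$min_gap,
                         dc = -cfg$min_gap:cfg$min_gap)
  truth <- list()
  for (k in seq_along(nuclei)) {
    nuc <- nuclei[[k]]
    placed <- FALSE
    for (try in seq_len(200L)) {
      ext <- ceiling(sqrt(nuc$area * nuc$axis_ratio / pi)) + margin
      if (2 * ext >= min(h, w)) stop("nucleus too large for the image")
      r0 <- stats::runif(1, ext, h - ext)
      c0 <- stats::runif(1, ext, w - ext)
      px <- ellipse_pixels(r0, c0, nuc$area, nuc$axis_ratio, nuc$theta, h, w)
      rows <- (px - 1L) %% h + 1L
      cols <- (px - 1L) %/% h + 1L
      # dilate by the minimum gap and test occupancy
      dil <- unique((pmin(pmax(rep(cols, each = nrow(gap_off)) +
                                 gap_off$dc, 1L), w) - 1L) * h +
                      pmin(pmax(rep(rows, each = nrow(gap_off)) +
                                  gap_off$dr, 1L), h))
      if (!any(occupied[dil])) {
        occupied[dil] <- TRUE
        lab[px] <- k
        red0[px] <- nuc$red_level
        green0[px] <- nuc$green_level
        blue0[px] <- nuc$dapi_level * dapi_gain
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place nucleus ", k,
                      " after 200 attempts; reduce n_nuclei or area")
    truth[[k]] <- data.frame(
      image_id = image_id, experiment_id = experiment_id, nucleus_id = k,
      true_state = nuc$state, true_area = length(px),
      red_level = nuc$red_level, green_level = nuc$green_level,
      dapi_level = nuc$dapi_level * dapi_gain, stringsAsFactors = FALSE)
  }
  maxv <- 2^cfg$bit_depth - 1
  quant <- function(m) pmin(pmax(round(m), 0), maxv)
  off <- cfg$background_offset
  # ground truth from quantized, noise-free planes (background removed)
  q_red <- quant(red0 + off); q_green <- quant(green0 + off)
  q_blue <- quant(blue0 + off)
  truth <- do.call(rbind, truth)
  if (!is.null(truth) && nrow(truth)) {
    truth$true_total_red <- vapply(seq_len(nrow(truth)), function(k)
      sum(q_red[lab == k] - round(off)), numeric(1))
    truth$true_total_green <- vapply(seq_len(nrow(truth)), function(k)
      sum(q_green[lab == k] - round(off)), numeric(1))
    truth$true_total_dapi <- vapply(seq_len(nrow(truth)), function(k)
      sum(q_blue[lab == k] - round(off)), numeric(1))
  } else {
    truth <- data.frame(image_id = character(0),
                        experiment_id = character(0),
                        nucleus_id = integer(0), true_state = character(0),
                        true_area = integer(0), red_level = numeric(0),
                        green_level = numeric(0), dapi_level = numeric(0),
                        true_total_red = numeric(0),
                        true_total_green = numeric(0),
                        true_total_dapi = numeric(0))
  }
  noisy <- function(m) {
    if (cfg$noise_sd > 0)
      m <- m + matrix(stats::rnorm(h * w, 0, cfg$noise_sd), h, w)
    quant(m)
  }
  img <- fluorescence_image(noisy(red0 + off), noisy(green0 + off),
                            noisy(blue0 + off), bit_depth = cfg$bit_depth,
                            image_id = image_id,
                            experiment_id = experiment_id)
  list(image = img, label_matrix = lab,
       masks = label_matrix_to_masks(lab), truth = truth)
}

#' Simulate one field of view (states, nuclei, rendering)
#'
#' @param cfg A [synthetic_config()].
#' @param image_id,experiment_id Identifiers.
#' @param seed Seed for this image's draws (default: derived from
#'   `cfg$seed`).
#' @param dapi_gain Per-experiment DAPI gain factor.
#' @return As [render_image()].
#' @export
simulate_image <- function(cfg = synthetic_config(), image_id = "img",
                           experiment_id = "exp", seed = cfg$seed,
                           dapi_gain = 1) {
  set.seed(seed)
  n <- if (length(cfg$n_nuclei) > 1L)
    sample(cfg$n_nuclei[1]:cfg$n_nuclei[2], 1L) else cfg$n_nuclei
  states <- sample_states(n, cfg)
  nuclei <- lapply(states, sample_nucleus, cfg = cfg)
  render_image(nuclei, cfg, image_id, experiment_id, dapi_gain)
}

#' Generate a full multi-experiment dataset on disk
#'
#' Writes `n_experiments * images_per_experiment` RGB images (PNG), one
#' labeled mask per image (PGM), a ground-truth CSV and a manifest CSV.
#' Per-experiment and per-image seeds are derived deterministically from
#' the master seed, so the same seed yields byte-identical files. With
#' `gain_jitter > 0` each experiment's DAPI plane is scaled by a uniform
#' gain factor, emulating acquisition variability that the per-image
#' feature normalization must absorb.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_experiments,images_per_experiment Dataset shape (default
#'   13 x 10, mirroring a 130-image cohort).
#' @param cfg A [synthetic_config()].
#' @return Invisibly, a list with `manifest` (data.frame), `truth`
#'   (data.frame), `gains` (per-experiment DAPI gain) and the file paths.
#' @export
generate_dataset <- function(out_dir, n_experiments = 13L,
                             images_per_experiment = 10L,
                             cfg = synthetic_config()) {
  stopifnot(n_experiments >= 1L, images_per_experiment >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(); truth <- list()
  gains <- numeric(n_experiments)
  for (e in seq_len(n_experiments)) {
    eid <- sprintf("exp%02d", e)
    set.seed(derive_seed(cfg$seed, e * 100000L))
    gains[e] <- if (cfg$gain_jitter > 0)
      stats::runif(1, 1 - cfg$gain_jitter, 1 + cfg$gain_jitter) else 1
    for (i in seq_len(images_per_experiment)) {
      iid <- sprintf("%s_img%02d", eid, i)
      sim <- simulate_image(cfg, image_id = iid, experiment_id = eid,
                            seed = derive_seed(cfg$seed, e * 100000L + i),
                            dapi_gain = gains[e])
      img_path <- file.path(out_dir, paste0(iid, ".png"))
      mask_path <- file.path(out_dir, paste0(iid, "_mask.pgm"))
      write_rgb_image(sim$image, img_path)
      write_label_mask(sim$label_matrix, mask_path)
      manifest[[iid]] <- data.frame(image_path = basename(img_path),
                                    mask_path = basename(mask_path),
                                    experiment_id = eid,
                                    stringsAsFactors = FALSE)
      truth[[iid]] <- sim$truth
    }
  }
  manifest <- do.call(rbind, manifest)
  truth <- do.call(rbind, truth)
  rownames(manifest) <- rownames(truth) <- NULL
  manifest_path <- file.path(out_dir, "manifest.csv")
  truth_path <- file.path(out_dir, "ground_truth.csv")
  write_manifest(manifest, manifest_path)
  utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  invisible(list(manifest = manifest, truth = truth, gains = gains,
                 manifest_path = manifest_path, truth_path = truth_path,
                 dir = out_dir))
}
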