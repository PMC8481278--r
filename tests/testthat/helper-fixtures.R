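# Small in-code fixtures shared across the suite.

# A deterministic 3-plane image with distinct, easily checked values.
tiny_image <- function(h = 4, w = 4, r = 7, g = 3, b = 5, bit_depth = 8L) {
  fluorescence_image(matrix(r, h, w), matrix(g, h, w), matrix(b, h, w),
                     bit_depth = bit_depth, image_id = "tiny",
                     experiment_id = "expA")
}

# Rectangular mask from row/col ranges (1-based, inclusive).
rect_mask <- function(rows, cols, dim, id = 1L) {
  px <- as.integer(outer(rows, (cols - 1L) * dim[1], `+`))
  nucleus_mask(px, dim, nucleus_id = id)
}

# A disk mask of the given radius centred at (r0, c0).
disk_mask <- function(r0, c0, radius, dim, id = 1L) {
  rows <- rep(seq_len(dim[1]), times = dim[2])
  cols <- rep(seq_len(dim[2]), each = dim[1])
  inside <- (rows - r0)^2 + (cols - c0)^2 <= radius^2
  nucleus_mask(which(inside), dim, nucleus_id = id)
}

# Feature rows with just the fields the labeler needs.
feature_row <- function(mean_red, mean_green, area,
                        image_id = "img1", experiment_id = "expA",
                        nucleus_id = 1L) {
  data.frame(image_id = image_id, experiment_id = experiment_id,
             nucleus_id = nucleus_id, area = area,
             total_dapi = area * 100, total_red = mean_red * area,
             total_green = mean_green * area, mean_red = mean_red,
             mean_green = mean_green,
             norm_red = NA_real_, norm_green = NA_real_,
             stringsAsFactors = FALSE)
}

# Independent brute-force metric reference used against the evaluation
# module: plain pair counting, no shared code.
brute_force_metrics <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

# A small labeled, normalized staging dataset for classifier tests:
# two clusters in (norm_area, norm_dapi) with controllable separation.
toy_staging_data <- function(n_per_class = 40, sep = 2, seed = 42,
                             n_images = 4) {
  set.seed(seed)
  n <- 2 * n_per_class
  lab <- rep(c("G1", "S_G2"), each = n_per_class)
  mu <- ifelse(lab == "G1", -sep / 2, sep / 2)
  data.frame(
    image_id = rep_len(sprintf("img%d", seq_len(n_images)), n),
    experiment_id = rep_len(sprintf("exp%d", 1:2), n),
    nucleus_id = seq_len(n),
    norm_area = stats::rnorm(n, mu, 0.5),
    norm_dapi = stats::rnorm(n, mu, 0.5),
    label = lab, stringsAsFactors = FALSE)
}
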