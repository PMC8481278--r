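#' Configuration of the automatic Fucci2 labeler
#'
#' Thresholds for the three exclusion criteria applied before the sign rule:
#' darkness (both mean Fucci intensities below `epsilon`), transition
#' (green/red ratio inside `(tau1, tau2)`), and aberrant area
#' (`|A - mean_A| > area_sigma_multiplier * sd_A`).
#'
#' @param epsilon Darkness threshold on the 8-bit intensity scale
#'   (default 40); automatically rescaled by `2^(bit_depth - 8)` when
#'   features come from deeper images.
#' @param tau1,tau2 Transition band bounds on the green/red ratio
#'   (defaults 0.9 and 1.1); requires `0 < tau1 < 1 < tau2`.
#' @param area_sigma_multiplier Multiplier on the area standard deviation
#'   (default 1, the literal `|A - mean| > sd` rule).
#' @param area_stats_scope `"per-cohort"` (default: one mean/sd over all
#'   input nuclei) or `"per-image"`.
#' @param dark_rule `"both"` (default: both channels must be below epsilon
#'   to call a nucleus colorless) or `"either"`.
#' @return A list of class `labeling_config`.
#' @export
labeling_config <- function(epsilon = 40, tau1 = 0.9, tau2 = 1.1,
                            area_sigma_multiplier = 1,
                            area_stats_scope = c("per-cohort", "per-image"),
                            dark_rule = c("both", "either")) {
  stopifnot(epsilon >= 0, tau1 > 0, tau1 < 1, tau2 > 1,
            area_sigma_multiplier > 0)
  structure(list(epsilon = epsilon, tau1 = tau1, tau2 = tau2,
                 area_sigma_multiplier = area_sigma_multiplier,
                 area_stats_scope = match.arg(area_stats_scope),
                 dark_rule = match.arg(dark_rule)),
            class = "labeling_config")
}

#' Cohort area statistics
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of the
#' nucleus areas, computed over the full cohort before any exclusion.
#'
#' @param features Feature data.frame with an `area` column (>= 2 rows).
#' @return List of class `area_stats` with `mean_area`, `std_area`, `n`.
#' @export
compute_area_stats <- function(features) {
  a <- features$area
  if (length(a) < 2L) stop("need >= 2 nuclei for area statistics")
  structure(list(mean_area = mean(a), std_area = stats::sd(a),
                 n = length(a)),
            class = "area_stats")
}

label_levels <- c("G1", "S_G2", "EXCLUDED")
exclusion_reasons <- c("none", "dark", "transition", "aberrant_area",
                       "ambiguous_tie", "undefined_color")

cycle_label <- function(state, reason = "none") {
  stopifnot(state %in% label_levels, reason %in% exclusion_reasons,
            (reason == "none") == (state != "EXCLUDED"))
  list(state = state, exclusion_reason = reason)
}

#' Apply the exclusion criteria to one nucleus
#'
#' Criteria are evaluated in fixed order and the first hit is recorded:
#' dark (both mean Fucci intensities `< epsilon`), transition (green/red
#' ratio strictly inside `(tau1, tau2)`; a zero red mean gives ratio
#' +Inf, never transition), aberrant area. A nucleus with undefined color
#' (both means zero) is excluded as dark by the first rule.
#'
#' @param f One-row feature data.frame (or list) with `mean_red`,
#'   `mean_green`, `area`.
#' @param stats An `area_stats` object for the cohort.
#' @param cfg A [labeling_config()].
#' @param epsilon Resolved darkness threshold (after any bit-depth
#'   rescaling); defaults to `cfg$epsilon`.
#' @return A label list with `state` and `exclusion_reason`; state
#'   `"PASS"` marks a nucleus that proceeds to the sign rule.
#' @export
apply_exclusion_criteria <- function(f, stats, cfg = labeling_config(),
                                     epsilon = cfg$epsilon) {
  mr <- f$mean_red; mg <- f$mean_green
  dark <- if (cfg$dark_rule == "both") (mr < epsilon && mg < epsilon)
          else (mr < epsilon || mg < epsilon)
  if (dark) return(cycle_label("EXCLUDED", "dark"))
  ratio <- if (mr > 0) mg / mr else Inf
  if (ratio > cfg$tau1 && ratio < cfg$tau2)
    return(cycle_label("EXCLUDED", "transition"))
  if (abs(f$area - stats$mean_area) >
      cfg$area_sigma_multiplier * stats$std_area)
    return(cycle_label("EXCLUDED", "aberrant_area"))
  list(state = "PASS", exclusion_reason = "none")
}

#' Sign rule on the mean Fucci intensities
#'
#' The decision boundary is the first-quadrant bisectrix of the red-green
#' plane: green above red means S/G2, red above green means G1. An exact
#' tie is flagged (unreachable under default thresholds, since ratio 1 sits
#' inside the transition band).
#'
#' @param f One-row feature data.frame (or list) with `mean_red`,
#'   `mean_green`.
#' @return A label list with `state` and `exclusion_reason`.
#' @export
assign_label <- function(f) {
  if (f$mean_green > f$mean_red) cycle_label("S_G2")
  else if (f$mean_red > f$mean_green) cycle_label("G1")
  else cycle_label("EXCLUDED", "ambiguous_tie")
}

#' Label a cohort of nuclei from Fucci2 features
#'
#' Computes area statistics once over all input nuclei (before any
#' exclusion), then applies the exclusion criteria and the sign rule per
#' nucleus. When `bit_depth != 8` the darkness threshold is rescaled by
#' `2^(bit_depth - 8)` and a message is emitted.
#'
#' @param features Feature data.frame (>= 2 rows) from
#'   [extract_features()].
#' @param cfg A [labeling_config()].
#' @param bit_depth Bit depth of the source images (default 8).
#' @return The input data.frame with `label` and `exclusion_reason`
#'   columns appended, order preserved.
#' @export
label_cohort <- function(features, cfg = labeling_config(), bit_depth = 8L) {
  eps <- cfg$epsilon
  if (bit_depth != 8L) {
    eps <- cfg$epsilon * 2^(bit_depth - 8)
    message(sprintf("darkness threshold rescaled to %g for %d-bit data",
                    eps, bit_depth))
  }
  stats_for <- function(rows) compute_area_stats(features[rows, ])
  if (cfg$area_stats_scope == "per-cohort") {
    st <- compute_area_stats(features)
    stats_of <- function(i) st
  } else {
    by_img <- split(seq_len(nrow(features)), features$image_id)
    st_img <- lapply(by_img, stats_for)
    img_of <- match(features$image_id, names(by_img))
    stats_of <- function(i) st_img[[img_of[i]]]
  }
  n <- nrow(features)
  lab <- character(n); reason <- character(n)
  for (i in seq_len(n)) {
    f <- features[i, ]
    res <- apply_exclusion_criteria(f, stats_of(i), cfg, epsilon = eps)
    if (res$state == "PASS") res <- assign_label(f)
    lab[i] <- res$state
    reason[i] <- res$exclusion_reason
  }
  features$label <- lab
  features$exclusion_reason <- reason
  features
}

#' Summarize cohort labels
#'
#' Counts per class and per exclusion reason, plus the percentage of G1 and
#' S/G2 among non-excluded nuclei (one-decimal reporting precision kept in
#' `pct_g1_rounded`/`pct_sg2_rounded`; exact values alongside).
#'
#' @param labels Character vector of states, or a labeled data.frame from
#'   [label_cohort()].
#' @return List with `n_g1`, `n_sg2`, `n_labeled`, `exclusions` (named
#'   counts), `pct_g1`, `pct_sg2` and their rounded versions (`NA` when no
#'   nucleus is labeled).
#' @export
summarize_labels <- function(labels) {
  if (is.data.frame(labels)) {
    states <- labels$label
    reasons <- labels$exclusion_reason
  } else {
    states <- labels
    reasons <- rep("none", length(labels))
  }
  n_g1 <- sum(states == "G1")
  n_sg2 <- sum(states == "S_G2")
  n_lab <- n_g1 + n_sg2
  excl <- table(factor(reasons[states == "EXCLUDED"],
                       levels = setdiff(exclusion_reasons, "none")))
  pct_g1 <- if (n_lab > 0) 100 * n_g1 / n_lab else NA_real_
  pct_sg2 <- if (n_lab > 0) 100 * n_sg2 / n_lab else NA_real_
  list(n_g1 = n_g1, n_sg2 = n_sg2, n_labeled = n_lab,
       exclusions = c(excl),
       pct_g1 = pct_g1, pct_sg2 = pct_sg2,
       pct_g1_rounded = round(pct_g1, 1), pct_sg2_rounded = round(pct_sg2, 1))
}

#' Agreement between two label vectors
#'
#' Restricts to nuclei labeled (non-excluded) in both lists, counts the
#' 2x2 confusion table and reports percent agreement
#' `100 * (N - divergences) / N`.
#'
#' @param auto,ref Character vectors of states aligned by nucleus.
#' @return List with `n_compared`, `n_divergent`, `confusion` (2x2 table,
#'   rows = auto, cols = ref) and `agreement_pct`.
#' @export
agreement_with_reference <- function(auto, ref) {
  if (length(auto) != length(ref)) stop("label vectors differ in length")
  keep <- auto %in% c("G1", "S_G2") & ref %in% c("G1", "S_G2")
  a <- factor(auto[keep], levels = c("G1", "S_G2"))
  r <- factor(ref[keep], levels = c("G1", "S_G2"))
  cm <- table(auto = a, ref = r)
  n <- sum(cm)
  div <- n - sum(diag(cm))
  list(n_compared = n, n_divergent = div, confusion = cm,
       agreement_pct = if (n > 0) 100 * (n - div) / n else NA_real_)
}
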