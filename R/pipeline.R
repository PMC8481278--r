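#' Process one field of view into per-nucleus features
#'
#' Runs the single-image part of the pipeline: segmentation (baseline
#' segmenter on the DAPI plane unless masks are supplied), border-nucleus
#' removal, mean-background estimation and subtraction, and feature
#' extraction on the background-subtracted planes.
#'
#' @param image A [fluorescence_image()].
#' @param masks Optional list of [nucleus_mask()] (e.g. from an external
#'   deep segmenter); when NULL the baseline segmenter runs.
#' @param seg_cfg A [segmenter_config()] for the baseline segmenter.
#' @param bg_subtract Subtract the per-channel mean background (default
#'   TRUE).
#' @param dapi_only Extract only area and integrated DAPI (deployment
#'   path).
#' @return Feature data.frame as from [extract_features()] (0 rows when
#'   nothing is segmented).
#' @export
process_image <- function(image, masks = NULL,
                          seg_cfg = segmenter_config(),
                          bg_subtract = TRUE, dapi_only = FALSE) {
  if (is.null(masks)) masks <- segment_baseline(image$blue, seg_cfg)
  masks <- remove_border_nuclei(masks, nrow(image$red), ncol(image$red))
  if (length(masks) == 0L)
    return(extract_features(image, list(), dapi_only = dapi_only))
  if (bg_subtract)
    image <- subtract_background(image, estimate_background_mean(image,
                                                                 masks))
  extract_features(image, masks, dapi_only = dapi_only)
}

#' Extract features for every image of a manifest
#'
#' @param manifest Data.frame from [read_manifest()] (or
#'   [generate_dataset()]).
#' @inheritParams process_image
#' @return Combined feature data.frame over all images.
#' @export
pipeline_features <- function(manifest, seg_cfg = segmenter_config(),
                              bg_subtract = TRUE, dapi_only = FALSE) {
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    img <- read_rgb_image(manifest$image_path[i],
                          experiment_id = manifest$experiment_id[i])
    masks <- if (!is.na(manifest$mask_path[i]))
      read_label_mask(manifest$mask_path[i]) else NULL
    out[[i]] <- process_image(img, masks, seg_cfg, bg_subtract, dapi_only)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Run the full labeling + staging preparation on a manifest
#'
#' Features are extracted for every image, the cohort is labeled from its
#' Fucci2 channels, excluded nuclei are dropped, and the staging features
#' are normalized per image. The result feeds [train_staging_model()],
#' [nested_kfold_cv()] or [leave_one_experiment_out_cv()] directly.
#'
#' @param manifest Data.frame from [read_manifest()].
#' @param seg_cfg A [segmenter_config()].
#' @param label_cfg A [labeling_config()].
#' @param bg_subtract Subtract the mean background first (default TRUE).
#' @return List with `features` (all nuclei, labeled), `staging` (labeled
#'   nuclei only, with `norm_area`/`norm_dapi`) and `label_summary`.
#' @export
prepare_staging_dataset <- function(manifest,
                                    seg_cfg = segmenter_config(),
                                    label_cfg = labeling_config(),
                                    bg_subtract = TRUE) {
  feats <- pipeline_features(manifest, seg_cfg, bg_subtract = bg_subtract)
  labeled <- label_cohort(feats, label_cfg)
  keep <- labeled$label %in% c("G1", "S_G2")
  staging <- normalize_per_image(labeled[keep, ])$features
  list(features = labeled, staging = staging,
       label_summary = summarize_labels(labeled))
}
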