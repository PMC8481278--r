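#' Confusion matrix for the two-phase problem
#' @param true_labels,predicted_labels Vectors over `{"G1","S_G2"}` of
#'   equal length.
#' @return 2x2 table, rows = true, cols = predicted.
#' @export
confusion_matrix <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  lv <- c("G1", "S_G2")
  if (!all(true_labels %in% lv) || !all(predicted_labels %in% lv))
    stop("labels must be G1 or S_G2")
  table(true = factor(true_labels, levels = lv),
        predicted = factor(predicted_labels, levels = lv))
}

#' Precision, recall and F1 for one class taken as positive
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; a zero
#' denominator yields 0 with a warning so fold aggregation stays defined.
#'
#' @param cm A 2x2 confusion matrix from [confusion_matrix()].
#' @param positive_class `"G1"` or `"S_G2"`.
#' @return Named vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(cm, positive_class = "G1") {
  stopifnot(positive_class %in% rownames(cm))
  tp <- cm[positive_class, positive_class]
  fp <- sum(cm[, positive_class]) - tp
  fn <- sum(cm[positive_class, ]) - tp
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as 0")
      return(0)
    }
    num / den
  }
  p <- safe(tp, tp + fp, "precision")
  r <- safe(tp, tp + fn, "recall")
  f1 <- if (p + r == 0) {
    warning("F1 undefined (precision + recall = 0); reported as 0")
    0
  } else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Macro-average F1 between the two classes
#' @param true_labels,predicted_labels Vectors over `{"G1","S_G2"}`.
#' @return Unweighted mean of the G1 and S/G2 F1 scores.
#' @export
macro_f1 <- function(true_labels, predicted_labels) {
  cm <- confusion_matrix(true_labels, predicted_labels)
  mean(c(precision_recall_f1(cm, "G1")["f1"],
         precision_recall_f1(cm, "S_G2")["f1"]))
}

# Full per-class metric set for one test fold.
fold_metrics <- function(true_labels, predicted_labels) {
  cm <- confusion_matrix(true_labels, predicted_labels)
  g1 <- precision_recall_f1(cm, "G1")
  sg2 <- precision_recall_f1(cm, "S_G2")
  data.frame(precision_g1 = g1["precision"], recall_g1 = g1["recall"],
             f1_g1 = g1["f1"], precision_sg2 = sg2["precision"],
             recall_sg2 = sg2["recall"], f1_sg2 = sg2["f1"],
             precision_avg = mean(c(g1["precision"], sg2["precision"])),
             recall_avg = mean(c(g1["recall"], sg2["recall"])),
             f1_avg = mean(c(g1["f1"], sg2["f1"])),
             n = length(true_labels), row.names = NULL)
}

# Split image ids into k seeded folds of near-equal size.
image_folds <- function(image_ids, k, seed) {
  ids <- unique(image_ids)
  if (length(ids) < k) stop("fewer images than folds")
  set.seed(seed)
  shuffled <- sample(ids)
  split(shuffled, rep_len(seq_len(k), length(shuffled)))
}

run_cv <- function(data, fold_of, cfg, quiet = TRUE,
                   allow_unnormalized = FALSE) {
  folds <- sort(unique(fold_of))
  per_fold <- vector("list", length(folds))
  per_image <- list()
  for (fi in seq_along(folds)) {
    test <- fold_of == folds[fi]
    train_df <- data[!test, ]
    test_df <- data[test, ]
    if (length(unique(test_df$label)) < 2L)
      warning("fold ", folds[fi], " contains a single class; ",
              "its per-class metrics are degenerate")
    model <- train_staging_model(train_df, cfg)
    pred <- predict(model, test_df, allow_unnormalized = allow_unnormalized)
    fm <- suppressWarnings(fold_metrics(test_df$label, as.character(pred)))
    fm$fold <- folds[fi]
    fm$grid_index <- model$grid_index
    fm$kernel <- model$grid_point$kernel
    per_fold[[fi]] <- fm
    img_f1 <- vapply(split(seq_len(nrow(test_df)), test_df$image_id),
                     function(rows) suppressWarnings(
                       macro_f1(test_df$label[rows],
                                as.character(pred[rows]))),
                     numeric(1))
    per_image[[fi]] <- data.frame(fold = folds[fi],
                                  image_id = names(img_f1),
                                  macro_f1 = unname(img_f1),
                                  stringsAsFactors = FALSE)
    if (!quiet)
      message(sprintf("fold %s: macro-F1 %.3f (%s)", folds[fi], fm$f1_avg,
                      fm$kernel))
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- setdiff(names(per_fold), c("fold", "grid_index", "kernel",
                                            "n"))
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(cn) mean(per_fold[[cn]]), numeric(1)),
    sd = vapply(metric_cols, function(cn) stats::sd(per_fold[[cn]]),
                numeric(1)),
    row.names = NULL)
  structure(list(per_fold = per_fold, summary = summary,
                 per_image = do.call(rbind, per_image)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Nested k-fold cross-validation of the staging pipeline
#'
#' Outer folds are drawn at the image level (per-image normalization
#' couples the nuclei of an image, so nucleus-level folds would leak
#' normalization statistics). For each held-out fold a model is selected
#' and trained on the remaining folds via [train_staging_model()] — the
#' inner 80/20 validation split — and scored on the fold.
#'
#' @param data Labeled, normalized feature data.frame (`label` restricted
#'   to G1/S_G2) with `image_id`, `norm_area`, `norm_dapi`.
#' @param k Number of outer folds (default 5).
#' @param cfg A [training_config()].
#' @param seed Seed for the image-level fold assignment (default
#'   `cfg$seed`).
#' @param quiet Suppress per-fold progress messages.
#' @param allow_unnormalized Permit raw (un-z-scored) feature columns;
#'   only for ablation studies of the per-image normalization.
#' @return An `evaluation_report`: per-fold metrics, mean +/- sd summary,
#'   and per-image macro-F1 values.
#' @export
nested_kfold_cv <- function(data, k = 5, cfg = training_config(),
                            seed = cfg$seed, quiet = TRUE,
                            allow_unnormalized = FALSE) {
  stopifnot(k >= 2)
  folds <- image_folds(data$image_id, k, seed)
  fold_of <- rep(NA_integer_, nrow(data))
  for (fi in seq_along(folds))
    fold_of[data$image_id %in% folds[[fi]]] <- fi
  run_cv(data, fold_of, cfg, quiet, allow_unnormalized)
}

#' Nested leave-one-experiment-out cross-validation
#'
#' One outer fold per experiment (acquisition batch): the model is trained
#' on all other experiments and tested on the held-out one. Per-image
#' macro-F1 values are retained for distribution summaries.
#'
#' @inheritParams nested_kfold_cv
#' @return An `evaluation_report` with one fold per experiment.
#' @export
leave_one_experiment_out_cv <- function(data, cfg = training_config(),
                                        quiet = TRUE,
                                        allow_unnormalized = FALSE) {
  exps <- unique(data$experiment_id)
  if (length(exps) < 2L) stop("need >= 2 experiments")
  run_cv(data, match(data$experiment_id, exps), cfg, quiet,
         allow_unnormalized)
}

#' Distribution summary of per-image F1 scores
#'
#' Five-number summary plus outliers by the 1.5 IQR rule — the statistics
#' behind a box/violin plot of per-image performance.
#'
#' @param f1_values Numeric vector of per-image macro-F1 scores.
#' @return List with `median`, `q1`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high` and `outliers`.
#' @export
f1_distribution_summary <- function(f1_values) {
  q <- stats::quantile(f1_values, c(0.25, 0.5, 0.75), names = FALSE,
                       type = 7)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- f1_values[f1_values >= lo & f1_values <= hi]
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = f1_values[f1_values < lo | f1_values > hi])
}

#' Cell-cycle profile of total DAPI intensity
#'
#' Histogram of integrated DAPI intensity per labeled class over shared
#' bin edges — the in-situ analogue of a flow-cytometry DNA profile, with
#' the S/G2 mode at higher intensity than G1.
#'
#' @param labeled Data.frame with `total_dapi` and `label` columns
#'   (G1/S_G2 rows are used).
#' @param n_bins Number of equal-width bins (default 30).
#' @return List with `breaks` (length `n_bins + 1`) and `counts`
#'   (2 x n_bins matrix, rows G1 and S_G2).
#' @export
dapi_intensity_histogram <- function(labeled, n_bins = 30) {
  keep <- labeled$label %in% c("G1", "S_G2")
  if (!any(keep)) stop("no labeled nuclei")
  v <- labeled$total_dapi[keep]
  lab <- labeled$label[keep]
  rng <- range(v)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- rbind(
    G1 = tabulate(bin[lab == "G1"], n_bins),
    S_G2 = tabulate(bin[lab == "S_G2"], n_bins))
  list(breaks = breaks, counts = counts)
}
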