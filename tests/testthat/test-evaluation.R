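test_that("confusion matrix counts (true, predicted) pairs", {
  lv <- rep(c("G1", "S_G2"), each = 5)
  cm <- confusion_matrix(lv, lv)
  expect_equal(diag(cm), c(G1 = 5, S_G2 = 5), ignore_attr = TRUE)
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  cm2 <- confusion_matrix(rep("G1", 4), rep("S_G2", 4))
  expect_equal(cm2["G1", "S_G2"], 4, ignore_attr = TRUE)
  expect_error(confusion_matrix("G1", c("G1", "G1")), "length")
  expect_error(confusion_matrix("G1", "M"), "labels")
  # brute-force pair counting on random vectors
  set.seed(24)
  a <- sample(c("G1", "S_G2"), 30, replace = TRUE)
  b <- sample(c("G1", "S_G2"), 30, replace = TRUE)
  cm3 <- confusion_matrix(a, b)
  for (ta in c("G1", "S_G2")) for (pb in c("G1", "S_G2")) {
    cnt <- 0L
    for (i in 1:30) if (a[i] == ta && b[i] == pb) cnt <- cnt + 1L
    expect_equal(unname(cm3[ta, pb]), cnt, ignore_attr = TRUE)
  }
})

test_that("precision/recall/F1 match hand arithmetic and conventions", {
  # TP=9, FP=1, FN=3 with G1 positive
  truth <- c(rep("G1", 12), rep("S_G2", 8))
  pred <- c(rep("G1", 9), rep("S_G2", 3), "G1", rep("S_G2", 7))
  m <- precision_recall_f1(confusion_matrix(truth, pred), "G1")
  expect_equal(unname(m), c(0.9, 0.75, 2 * 0.9 * 0.75 / 1.65),
               tolerance = 1e-12)
  perfect <- precision_recall_f1(confusion_matrix(truth, truth), "S_G2")
  expect_equal(unname(perfect), c(1, 1, 1))
  # empty positive predictions: all metrics 0 with warnings
  expect_warning(
    z <- precision_recall_f1(
      confusion_matrix(rep("G1", 5), rep("S_G2", 5)), "G1"),
    "undefined")
  expect_equal(unname(z), c(0, 0, 0))
})

test_that("metrics agree with a brute-force reference on random vectors", {
  set.seed(25)
  for (r in 1:100) {
    n <- sample(5:40, 1)
    truth <- sample(c("G1", "S_G2"), n, replace = TRUE)
    pred <- sample(c("G1", "S_G2"), n, replace = TRUE)
    cm <- confusion_matrix(truth, pred)
    for (pos in c("G1", "S_G2")) {
      got <- suppressWarnings(precision_recall_f1(cm, pos))
      expect_equal(unname(got), unname(brute_force_metrics(truth, pred,
                                                           pos)),
                   tolerance = 1e-12)
    }
    expect_equal(suppressWarnings(macro_f1(truth, pred)),
                 mean(c(brute_force_metrics(truth, pred, "G1")["f1"],
                        brute_force_metrics(truth, pred, "S_G2")["f1"])),
                 tolerance = 1e-12)
  }
})

test_that("k-fold CV partitions images exactly once and is deterministic", {
  data <- toy_staging_data(n_per_class = 60, sep = 3, n_images = 10)
  cfg <- training_config(seed = 6)
  r1 <- nested_kfold_cv(data, k = 5, cfg)
  expect_identical(nrow(r1$per_fold), 5L)
  # every image tested exactly once
  tested <- r1$per_image$image_id
  expect_setequal(tested, unique(data$image_id))
  expect_identical(anyDuplicated(tested), 0L)
  # every nucleus in exactly one test fold
  expect_identical(sum(r1$per_fold$n), nrow(data))
  r2 <- nested_kfold_cv(data, k = 5, cfg)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_error(nested_kfold_cv(data, k = 20, cfg), "fewer images")
})

test_that("separable toy experiments give per-image macro-F1 of 1", {
  data <- toy_staging_data(n_per_class = 45, sep = 5, n_images = 6)
  data$experiment_id <- rep_len(sprintf("exp%d", 1:3), nrow(data))
  rep <- leave_one_experiment_out_cv(data, training_config(seed = 7))
  expect_identical(nrow(rep$per_fold), 3L)
  expect_setequal(rep$per_image$image_id, unique(data$image_id))
  expect_true(all(rep$per_image$macro_f1 == 1))
  expect_error(
    leave_one_experiment_out_cv(data[data$experiment_id == "exp1", ]),
    ">= 2 experiments")
})

test_that("single-class test folds are flagged and degrade gracefully", {
  data <- toy_staging_data(n_per_class = 40, sep = 4, n_images = 8)
  data$experiment_id <- ifelse(data$label == "G1" &
                                 data$image_id == "img1", "expZ",
                               rep_len(c("expA", "expB"), nrow(data)))
  expect_warning(rep <- leave_one_experiment_out_cv(
    data, training_config(seed = 8)), "single class")
  expect_identical(nrow(rep$per_fold), 3L)
})

test_that("F1 distribution summary implements the 1.5 IQR rule", {
  v <- c(0.2, 0.85, 0.9, 0.92, 0.93, 0.95, 0.97, 1.0)
  s <- f1_distribution_summary(v)
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(s$median, q[2])
  expect_equal(s$iqr, q[3] - q[1])
  expect_true(0.2 %in% s$outliers)
  expect_gte(s$whisker_low, q[1] - 1.5 * s$iqr)
})

test_that("the DAPI profile shows S/G2 at higher intensity than G1", {
  # all equal values collapse into one bin and counts are conserved
  one <- data.frame(total_dapi = rep(100, 7),
                    label = c(rep("G1", 4), rep("S_G2", 3)))
  h1 <- dapi_intensity_histogram(one, n_bins = 10)
  expect_identical(sum(h1$counts), 7L)
  expect_identical(sum(colSums(h1$counts) > 0), 1L)
  # synthetic cohort (pooled over images so both classes survive
  # exclusion): class-weighted mean of S/G2 bins above G1 bins
  df <- do.call(rbind, lapply(51:53, function(s) {
    sim <- simulate_image(synthetic_config(seed = s), seed = s)
    img <- subtract_background(sim$image,
                               estimate_background_mean(sim$image,
                                                        sim$masks))
    extract_features(img, sim$masks)
  }))
  df <- label_cohort(df)
  h <- dapi_intensity_histogram(df, n_bins = 20)
  mids <- (h$breaks[-1] + h$breaks[-21]) / 2
  mean_g1 <- sum(mids * h$counts["G1", ]) / sum(h$counts["G1", ])
  mean_sg2 <- sum(mids * h$counts["S_G2", ]) / sum(h$counts["S_G2", ])
  expect_gt(mean_sg2, mean_g1)
  expect_identical(sum(h$counts), sum(df$label %in% c("G1", "S_G2")))
})
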