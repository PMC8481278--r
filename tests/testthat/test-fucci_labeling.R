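test_that("area statistics use the sample (n-1) standard deviation", {
  f <- function(a) data.frame(area = a)
  s <- compute_area_stats(f(c(100, 100, 100)))
  expect_equal(s$mean_area, 100)
  expect_equal(s$std_area, 0)
  s2 <- compute_area_stats(f(c(90, 110)))
  expect_equal(s2$mean_area, 100)
  expect_equal(s2$std_area, sqrt(((90 - 100)^2 + (110 - 100)^2) / 1))
  set.seed(8)
  a <- rnorm(200, 250, 40)
  s3 <- compute_area_stats(f(a))
  expect_equal(s3$std_area, sqrt(sum((a - mean(a))^2) / (length(a) - 1)))
  expect_error(compute_area_stats(f(100)), ">= 2")
})

test_that("exclusion criteria fire in fixed order with recorded reasons", {
  stats <- structure(list(mean_area = 100, std_area = 50, n = 100),
                     class = "area_stats")
  cfg <- labeling_config()
  lab <- function(mr, mg, a) apply_exclusion_criteria(
    feature_row(mr, mg, a), stats, cfg)
  expect_identical(lab(30, 35, 100)$exclusion_reason, "dark")
  expect_identical(lab(100, 105, 100)$exclusion_reason, "transition")
  expect_identical(lab(200, 50, 300)$exclusion_reason, "aberrant_area")
  expect_identical(lab(200, 50, 100)$state, "PASS")
  # dark wins over transition when both hold
  expect_identical(lab(30, 31, 300)$exclusion_reason, "dark")
  # zero red mean: ratio +Inf, never a transition
  expect_identical(lab(0, 200, 100)$state, "PASS")
  # band edges are open: ratio exactly tau1 or tau2 is not a transition
  expect_identical(lab(100, 90, 100)$state, "PASS")
  expect_identical(lab(100, 110, 100)$state, "PASS")
})

test_that("the sign rule follows the red-green bisectrix", {
  expect_identical(assign_label(feature_row(50, 120, 100))$state, "S_G2")
  expect_identical(assign_label(feature_row(120, 50, 100))$state, "G1")
  tie <- assign_label(feature_row(200, 200, 100))
  expect_identical(tie$state, "EXCLUDED")
  expect_identical(tie$exclusion_reason, "ambiguous_tie")
})

test_that("label_cohort partitions every nucleus exactly once", {
  set.seed(16)
  n <- 60
  feats <- do.call(rbind, lapply(seq_len(n), function(i)
    feature_row(runif(1, 0, 255), runif(1, 0, 255),
                rnorm(1, 100, 30), nucleus_id = i)))
  out <- label_cohort(feats)
  expect_identical(nrow(out), as.integer(n))
  s <- summarize_labels(out)
  expect_identical(s$n_g1 + s$n_sg2 + sum(s$exclusions), as.integer(n))
  expect_true(all(out$exclusion_reason[out$label != "EXCLUDED"] == "none"))
  expect_true(all(out$exclusion_reason[out$label == "EXCLUDED"] != "none"))
})

test_that("sign-rule labels are invariant to Fucci gain, darkness is not", {
  f1 <- feature_row(60, 45, 100, nucleus_id = 1L)
  f2 <- feature_row(45, 60, 100, nucleus_id = 2L)
  cohort <- rbind(f1, f2)
  out1 <- label_cohort(cohort)
  scaled <- cohort
  for (cn in c("mean_red", "mean_green", "total_red", "total_green"))
    scaled[[cn]] <- scaled[[cn]] * 3
  expect_identical(label_cohort(scaled)$label, out1$label)
  # scaling down pushes both below epsilon: darkness is scale-dependent
  shrunk <- cohort
  for (cn in c("mean_red", "mean_green", "total_red", "total_green"))
    shrunk[[cn]] <- shrunk[[cn]] / 3
  expect_true(all(label_cohort(shrunk)$exclusion_reason == "dark"))
})

test_that("permissive thresholds reduce labeling to the sign rule", {
  set.seed(17)
  n <- 80
  feats <- do.call(rbind, lapply(seq_len(n), function(i)
    feature_row(runif(1, 0, 255), runif(1, 0, 255),
                rnorm(1, 100, 50), nucleus_id = i)))
  cfg <- labeling_config(epsilon = 0, tau1 = 1 - 1e-12, tau2 = 1 + 1e-12,
                         area_sigma_multiplier = 1e12)
  out <- label_cohort(feats, cfg)
  expect_true(all(out$label %in% c("G1", "S_G2")))
  expect_identical(out$label,
                   ifelse(feats$mean_green > feats$mean_red, "S_G2", "G1"))
})

test_that("all-dark cohorts are entirely excluded as dark", {
  feats <- rbind(feature_row(10, 12, 100, nucleus_id = 1L),
                 feature_row(5, 2, 110, nucleus_id = 2L),
                 feature_row(0, 0, 90, nucleus_id = 3L))
  out <- label_cohort(feats)
  expect_true(all(out$label == "EXCLUDED"))
  expect_true(all(out$exclusion_reason == "dark"))
})

test_that("non-excluded labels match generator truth on a synthetic cohort", {
  acc_num <- 0L; acc_den <- 0L
  for (s in 41:43) {
    sim <- simulate_image(synthetic_config(seed = s), seed = s)
    img <- subtract_background(sim$image,
                               estimate_background_mean(sim$image,
                                                        sim$masks))
    df <- label_cohort(extract_features(img, sim$masks))
    truth <- sim$truth$true_state[match(df$nucleus_id,
                                        sim$truth$nucleus_id)]
    ok <- df$label %in% c("G1", "S_G2") & truth %in% c("G1", "S_G2")
    acc_num <- acc_num + sum(df$label[ok] == truth[ok])
    acc_den <- acc_den + sum(ok)
  }
  expect_gt(acc_den, 50)
  expect_gte(acc_num / acc_den, 0.99)
})

test_that("label summaries report counts and one-decimal percentages", {
  s <- summarize_labels(c(rep("G1", 3), rep("S_G2", 1), "EXCLUDED"))
  expect_identical(s$n_labeled, 4L)
  expect_equal(s$pct_g1, 75)
  all_g1 <- summarize_labels(rep("G1", 5))
  expect_equal(all_g1$pct_g1_rounded, 100.0)
  expect_equal(all_g1$pct_sg2_rounded, 0.0)
  none <- summarize_labels(rep("EXCLUDED", 3))
  expect_true(is.na(none$pct_g1))
})

test_that("agreement restricts to doubly labeled nuclei and counts divergences", {
  auto <- c("G1", "G1", "S_G2", "EXCLUDED", "S_G2")
  ref <- c("G1", "S_G2", "S_G2", "G1", "EXCLUDED")
  agr <- agreement_with_reference(auto, ref)
  expect_identical(agr$n_compared, 3L)
  expect_identical(agr$n_divergent, 1L)
  expect_equal(agr$agreement_pct, 100 * 2 / 3)
  ident <- agreement_with_reference(auto, auto)
  expect_equal(ident$agreement_pct, 100)
  # 10 aligned nuclei, 3 divergent by construction, brute-force checked
  set.seed(18)
  a <- sample(c("G1", "S_G2"), 10, replace = TRUE)
  b <- a
  flip <- sample(10, 3)
  b[flip] <- ifelse(a[flip] == "G1", "S_G2", "G1")
  agr2 <- agreement_with_reference(a, b)
  ref_div <- 0L
  for (i in 1:10) if (a[i] != b[i]) ref_div <- ref_div + 1L
  expect_identical(agr2$n_divergent, ref_div)
  expect_equal(agr2$agreement_pct, 70)
  expect_error(agreement_with_reference(a, b[1:5]), "length")
})
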