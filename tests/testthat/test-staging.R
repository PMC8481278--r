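test_that("per-image normalization yields zero mean, unit variance", {
  df <- data.frame(image_id = "a", area = c(2, 4, 6),
                   total_dapi = c(10, 20, 60))
  out <- normalize_per_image(df)$features
  expect_equal(out$norm_area, c(-1, 0, 1) * 2 / sqrt(8 / 3),
               tolerance = 1e-9)
  expect_equal(out$norm_area[3], 1.22474487, tolerance = 1e-6)
  expect_equal(mean(out$norm_dapi), 0, tolerance = 1e-9)
  expect_equal(mean(out$norm_dapi^2), 1, tolerance = 1e-9)
})

test_that("degenerate images normalize to zero with a warning", {
  df <- data.frame(image_id = c("a", "a", "b"),
                   area = c(5, 5, 7), total_dapi = c(1, 2, 3))
  expect_warning(out <- normalize_per_image(df), "zero feature spread")
  expect_equal(out$features$norm_area[1:2], c(0, 0))   # sd = 0
  expect_equal(out$features$norm_area[3], 0)           # single nucleus
})

test_that("images are normalized independently of each other", {
  set.seed(19)
  df <- data.frame(image_id = rep(c("a", "b"), each = 5),
                   area = runif(10, 100, 400),
                   total_dapi = runif(10, 1e4, 4e4))
  joint <- normalize_per_image(df)$features
  alone <- normalize_per_image(df[df$image_id == "b", ])$features
  expect_equal(joint$norm_area[6:10], alone$norm_area)
  expect_equal(joint$norm_dapi[6:10], alone$norm_dapi)
})

test_that("class weights are inversely proportional to frequency", {
  expect_equal(unname(compute_class_weights(50, 50)), c(1, 1))
  w <- compute_class_weights(2291, 1262)
  expect_equal(unname(w), c(3553 / (2 * 2291), 3553 / (2 * 1262)),
               tolerance = 1e-12)
  expect_equal(unname(w), c(0.77543, 1.40768), tolerance = 1e-5)
  expect_equal(unname(compute_class_weights(1, 3)), c(2, 2 / 3),
               tolerance = 1e-9)
  # algebraic identity: sum_i n_i w_i = n
  set.seed(20)
  for (r in 1:20) {
    n1 <- sample(1:5000, 1); n2 <- sample(1:5000, 1)
    w <- compute_class_weights(n1, n2)
    expect_equal(n1 * w[["G1"]] + n2 * w[["S_G2"]], n1 + n2,
                 tolerance = 1e-9)
  }
  expect_error(compute_class_weights(0, 5), "at least one")
})

test_that("the hyperparameter grid matches the default search space", {
  g <- default_svm_grid()
  cs <- c(0.001, 0.10, 0.1, 10, 25, 50, 100, 1000)
  expect_identical(nrow(g), 4L * 8L + 8L * 5L + 4L * 8L + 8L)
  expect_identical(unique(g$kernel), c("rbf", "poly", "sigmoid", "linear"))
  expect_equal(g$C[g$kernel == "rbf"], rep(cs, 4))
  expect_equal(unique(g$gamma[g$kernel == "rbf"]),
               c(1e-2, 1e-3, 1e-4, 1e-5))
  expect_equal(g$degree[g$kernel == "poly"], rep(1:5, 8))
  expect_true(all(is.na(g$gamma[g$kernel %in% c("linear", "poly")])))
})

test_that("the SVM solver agrees with its KKT conditions", {
  set.seed(22)
  x <- rbind(matrix(rnorm(80, -1, 0.8), 40), matrix(rnorm(80, 1, 0.8), 40))
  y <- rep(c("G1", "S_G2"), each = 40)
  cw <- compute_class_weights(40, 40)
  for (kt in c("linear", "rbf")) {
    m <- weighted_svm(x, y, C = 5, class_weights = cw, kernel = kt,
                      gamma = 0.5, tol = 1e-4)
    yi <- ifelse(y == "G1", 1, -1)
    # dual feasibility: 0 <= alpha <= C_i and sum alpha_i y_i = 0
    alpha <- rep(0, nrow(x))
    alpha[match(apply(m$sv_x, 1, paste, collapse = ","),
                apply(x, 1, paste, collapse = ","))] <- m$sv_alpha
    expect_true(all(alpha >= -1e-9 & alpha <= 5 * cw["G1"] + 1e-9))
    expect_equal(sum(alpha * yi), 0, tolerance = 1e-6)
    # complementary slackness: free SVs lie on the margin |f| = 1
    f <- svm_decision(m, x)
    free <- alpha > 1e-6 & alpha < 5 * min(cw) - 1e-6
    if (any(free))
      expect_equal(yi[free] * f[free], rep(1, sum(free)), tolerance = 5e-3)
    # primal feasibility: alpha = 0 points satisfy y f >= 1 - tol
    expect_true(all(yi[alpha < 1e-9] * f[alpha < 1e-9] >= 1 - 1e-2))
  }
})

test_that("the SVM decision function matches an independent implementation", {
  # scikit-learn (preinstalled) solves the identical weighted dual; its
  # decision values on a frozen fixture are an external oracle.
  set.seed(7)
  x <- rbind(matrix(rnorm(60, -0.8, 1), 30), matrix(rnorm(60, 0.8, 1), 30))
  y <- rep(c("G1", "S_G2"), each = 30)
  m <- weighted_svm(x, y, C = 10, class_weights = c(G1 = 0.8, S_G2 = 1.4),
                    kernel = "rbf", gamma = 0.01)
  d <- svm_decision(m, x)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x1 = x[, 1], x2 = x[, 2],
                              y = ifelse(y == "G1", 1, -1)), csv,
                   row.names = FALSE)
  out <- tempfile()
  script <- sprintf(paste0(
    "import pandas as pd\nfrom sklearn.svm import SVC\n",
    "df = pd.read_csv('%s')\n",
    "m = SVC(C=10, kernel='rbf', gamma=0.01, ",
    "class_weight={1: 0.8, -1: 1.4}).fit(df[['x1','x2']], df['y'])\n",
    "pd.DataFrame({'dec': m.decision_function(df[['x1','x2']])})",
    ".to_csv('%s', index=False)\n"), csv, out)
  py <- tempfile(fileext = ".py")
  writeLines(script, py)
  status <- system2("python", py, stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  ref <- utils::read.csv(out)$dec
  expect_equal(d, ref, tolerance = 1e-4)
})

test_that("training is deterministic and separable data reaches F1 = 1", {
  data <- toy_staging_data(n_per_class = 30, sep = 4)
  cfg <- training_config(seed = 3)
  m1 <- train_staging_model(data, cfg)
  m2 <- train_staging_model(data, cfg)
  expect_identical(m1$grid_index, m2$grid_index)
  expect_equal(m1$validation_score, 1.0)
  p1 <- predict(m1, data)
  expect_identical(p1, predict(m2, data))
  expect_identical(as.character(p1), data$label)
})

test_that("prediction rejects raw-looking features unless overridden", {
  data <- toy_staging_data(sep = 4)
  m <- train_staging_model(data, training_config(seed = 1))
  raw <- data.frame(norm_area = c(250, 300), norm_dapi = c(2e4, 4e4))
  expect_error(predict(m, raw), "normalized")
  expect_length(predict(m, raw, allow_unnormalized = TRUE), 2)
  empty <- data[0, c("norm_area", "norm_dapi")]
  expect_length(predict(m, empty), 0)
})

test_that("prediction geometry follows the trained classes", {
  data <- toy_staging_data(n_per_class = 50, sep = 3)
  m <- train_staging_model(data, training_config(seed = 2))
  nd <- data.frame(norm_area = c(2, -2), norm_dapi = c(2, -2))
  p <- predict(m, nd)
  expect_identical(as.character(p), c("S_G2", "G1"))
})

test_that("prediction is invariant to per-image affine gain on raw data", {
  set.seed(23)
  df <- data.frame(image_id = rep("a", 30),
                   area = rnorm(30, 300, 50),
                   total_dapi = rnorm(30, 3e4, 6e3))
  n1 <- normalize_per_image(df)$features
  df2 <- df
  df2$total_dapi <- df2$total_dapi * 3   # e.g. DAPI plane scaled by 3
  n2 <- normalize_per_image(df2)$features
  expect_equal(n1$norm_dapi, n2$norm_dapi, tolerance = 1e-9)
  data <- toy_staging_data(sep = 3)
  m <- train_staging_model(data, training_config(seed = 1))
  expect_identical(predict(m, n1), predict(m, n2))
})

test_that("model JSON round trip preserves predictions; bad version fails", {
  data <- toy_staging_data(sep = 2, seed = 9)
  m <- train_staging_model(data, training_config(seed = 4))
  path <- tempfile(fileext = ".json")
  save_staging_model(m, path)
  back <- load_staging_model(path)
  expect_identical(predict(back, data), predict(m, data))
  expect_identical(back$grid_point$kernel, m$grid_point$kernel)
  bad <- jsonlite::read_json(path)
  bad$version <- 99
  jsonlite::write_json(bad, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_staging_model(path), "version-1")
})
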