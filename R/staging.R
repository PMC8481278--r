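#' Per-image z-score normalization of the staging features
#'
#' For each image separately, the nucleus area and the integrated DAPI
#' intensity are centered and scaled to zero mean and unit variance
#' (population standard deviation, as a standard feature scaler uses).
#' This removes per-acquisition gain and magnification differences; only
#' the within-image contrast between G1 and S/G2 nuclei remains. Images
#' with a single nucleus or zero spread get normalized value 0 with a
#' warning: relative contrast is undefined there.
#'
#' @param features Data.frame with `image_id`, `area`, `total_dapi`.
#' @return List with `features` (input plus `norm_area`, `norm_dapi`) and
#'   `normalizer` (per-image means and standard deviations).
#' @export
normalize_per_image <- function(features) {
  if (nrow(features) == 0L) stop("no features to normalize")
  zs <- function(v) {
    if (length(v) < 2L) return(list(z = 0 * v, mu = mean(v), sd = 0,
                                    degenerate = TRUE))
    mu <- mean(v)
    sdv <- sqrt(mean((v - mu)^2))
    if (sdv == 0) return(list(z = 0 * v, mu = mu, sd = 0, degenerate = TRUE))
    list(z = (v - mu) / sdv, mu = mu, sd = sdv, degenerate = FALSE)
  }
  ids <- unique(features$image_id)
  features$norm_area <- NA_real_
  features$norm_dapi <- NA_real_
  norm <- data.frame(image_id = ids, mean_area = NA_real_, sd_area = NA_real_,
                     mean_dapi = NA_real_, sd_dapi = NA_real_,
                     stringsAsFactors = FALSE)
  degenerate <- character(0)
  for (i in seq_along(ids)) {
    rows <- which(features$image_id == ids[i])
    za <- zs(features$area[rows])
    zd <- zs(features$total_dapi[rows])
    features$norm_area[rows] <- za$z
    features$norm_dapi[rows] <- zd$z
    norm[i, 2:5] <- c(za$mu, za$sd, zd$mu, zd$sd)
    if (za$degenerate || zd$degenerate) degenerate <- c(degenerate, ids[i])
  }
  if (length(degenerate))
    warning("zero feature spread in image(s) ",
            paste(degenerate, collapse = ", "),
            "; normalized values set to 0")
  list(features = features, normalizer = norm)
}

#' Class weights inversely proportional to class frequency
#'
#' `w_i = n_samples / (n_classes * n_samples_i)` with two classes, so the
#' minority class gets the larger weight and
#' `sum_i n_samples_i * w_i = n_samples`.
#'
#' @param n_g1,n_sg2 Training-set counts per class (both >= 1).
#' @return Named vector `c(G1 = ..., S_G2 = ...)`.
#' @export
compute_class_weights <- function(n_g1, n_sg2) {
  if (n_g1 < 1 || n_sg2 < 1) stop("both classes need at least one sample")
  n <- n_g1 + n_sg2
  c(G1 = n / (2 * n_g1), S_G2 = n / (2 * n_sg2))
}

#' Hyperparameter grid and training configuration
#'
#' The default grid is the full search space of the staging method, expanded in kernel
#' order rbf, poly, sigmoid, linear with parameter lists in printed order
#' (ties in validation score are broken by this order). The poly and
#' sigmoid kernels use `gamma = 1/2` (one over the number of features) when
#' the grid does not vary gamma for them, and `coef0 = 0`.
#'
#' @param grid Data.frame with columns `kernel`, `C`, `gamma`, `degree`
#'   (NA where unused); defaults to [default_svm_grid()].
#' @param validation_fraction Fraction held out for model selection
#'   (default 0.2).
#' @param seed Seed for the stratified train/validation split.
#' @return A list of class `training_config`.
#' @export
training_config <- function(grid = default_svm_grid(),
                            validation_fraction = 0.2, seed = 0L) {
  stopifnot(nrow(grid) >= 1L, validation_fraction > 0,
            validation_fraction < 1)
  structure(list(grid = grid, validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' @rdname training_config
#' @export
default_svm_grid <- function() {
  cs <- c(0.001, 0.10, 0.1, 10, 25, 50, 100, 1000)
  gammas <- c(1e-2, 1e-3, 1e-4, 1e-5)
  block <- function(kernel, outer, inner) {
    g <- expand.grid(inner = inner$values, outer = outer$values,
                     KEEP.OUT.ATTRS = FALSE)  # first factor varies fastest
    out <- data.frame(kernel = kernel, C = NA_real_, gamma = NA_real_,
                      degree = NA_integer_, stringsAsFactors = FALSE)
    out <- out[rep(1, nrow(g)), ]
    out[[outer$name]] <- g$outer
    out[[inner$name]] <- g$inner
    out
  }
  grid <- rbind(
    block("rbf", list(name = "gamma", values = gammas),
          list(name = "C", values = cs)),
    block("poly", list(name = "C", values = cs),
          list(name = "degree", values = 1:5)),
    block("sigmoid", list(name = "gamma", values = gammas),
          list(name = "C", values = cs)),
    data.frame(kernel = "linear", C = cs, gamma = NA_real_,
               degree = NA_integer_, stringsAsFactors = FALSE))
  rownames(grid) <- NULL
  grid
}

# Stratified validation split: per class, a seeded sample of indices.
stratified_split <- function(y, fraction, seed) {
  idx_val <- integer(0)
  set.seed(seed)
  for (cl in levels(factor(y))) {
    rows <- which(y == cl)
    n_val <- max(1L, round(fraction * length(rows)))
    if (n_val >= length(rows)) n_val <- length(rows) - 1L
    idx_val <- c(idx_val, sort(sample(rows, n_val)))
  }
  sort(idx_val)
}

fit_grid_point <- function(x, y, gp, class_weights) {
  gamma <- if (is.na(gp$gamma)) NULL else gp$gamma
  weighted_svm(x, y, C = gp$C, class_weights = class_weights,
               kernel = gp$kernel, gamma = gamma,
               degree = if (is.na(gp$degree)) 3L else gp$degree)
}

#' Train the cell-cycle staging model
#'
#' Stratified 80/20 train/validation split (seeded), class weights computed
#' from the training-split class frequencies, every grid point fitted on
#' the training split and scored on the validation split by the macro
#' (unweighted) average F1 of G1 and S/G2. The winning point (first on
#' ties, in grid order) is refitted on the full data with weights from the
#' full class counts.
#'
#' @param features Data.frame with `norm_area`, `norm_dapi` from
#'   [normalize_per_image()] and a `label` column in `{"G1","S_G2"}`.
#' @param cfg A [training_config()].
#' @param quiet Suppress per-kernel progress messages.
#' @return An object of class `staging_model` holding the fitted SVM, the
#'   chosen grid point, its validation score and the split seed.
#' @export
train_staging_model <- function(features, cfg = training_config(),
                                quiet = TRUE) {
  stopifnot(all(c("norm_area", "norm_dapi", "label") %in% names(features)))
  y <- factor(features$label, levels = c("G1", "S_G2"))
  if (any(is.na(y))) stop("labels must be G1 or S_G2")
  if (min(table(y)) < 2L) stop("need >= 2 samples per class")
  x <- as.matrix(features[, c("norm_area", "norm_dapi")])
  val <- stratified_split(y, cfg$validation_fraction, cfg$seed)
  xt <- x[-val, , drop = FALSE]; yt <- droplevels(y[-val])
  xv <- x[val, , drop = FALSE]; yv <- y[val]
  cw <- compute_class_weights(sum(yt == "G1"), sum(yt == "S_G2"))
  best <- list(score = -Inf, index = NA_integer_)
  for (g in seq_len(nrow(cfg$grid))) {
    gp <- cfg$grid[g, ]
    fit <- suppressWarnings(fit_grid_point(xt, yt, gp, cw))
    pred <- predict(fit, xv)
    score <- suppressWarnings(macro_f1(yv, pred))
    if (!quiet)
      message(sprintf("grid %3d %-7s C=%-6g gamma=%-6g deg=%-2s F1=%.4f",
                      g, gp$kernel, gp$C, gp$gamma,
                      as.character(gp$degree), score))
    if (score > best$score) best <- list(score = score, index = g)
  }
  gp <- cfg$grid[best$index, ]
  cw_full <- compute_class_weights(sum(y == "G1"), sum(y == "S_G2"))
  final <- suppressWarnings(fit_grid_point(x, y, gp, cw_full))
  structure(list(svm = final, grid_point = gp, grid_index = best$index,
                 validation_score = best$score, seed = cfg$seed,
                 feature_names = c("norm_area", "norm_dapi"),
                 class_weights = cw_full),
            class = "staging_model")
}

#' @export
print.staging_model <- function(x, ...) {
  gp <- x$grid_point
  cat(sprintf(
    "<staging_model: %s kernel (C=%g, gamma=%s, degree=%s), val macro-F1=%.3f>\n",
    gp$kernel, gp$C, format(gp$gamma), format(gp$degree),
    x$validation_score))
  invisible(x)
}

#' Predict cell-cycle phase from normalized DAPI features
#'
#' Inputs must already be per-image normalized with
#' [normalize_per_image()] applied to the new image(s) themselves. A
#' magnitude heuristic rejects feature columns that look like raw pixel
#' counts or intensities; set `allow_unnormalized = TRUE` to bypass it
#' deliberately (ablations only).
#'
#' @param object A `staging_model`.
#' @param newdata Data.frame with `norm_area` and `norm_dapi` columns (or a
#'   2-column matrix in that order).
#' @param allow_unnormalized Skip the normalization sanity check.
#' @param ... Unused.
#' @return Factor of `G1`/`S_G2`, one per row (empty input gives empty
#'   output).
#' @export
predict.staging_model <- function(object, newdata,
                                  allow_unnormalized = FALSE, ...) {
  x <- if (is.data.frame(newdata))
    as.matrix(newdata[, object$feature_names]) else as.matrix(newdata)
  if (nrow(x) == 0L)
    return(factor(character(0), levels = c("G1", "S_G2")))
  if (!allow_unnormalized && any(abs(x) > 20))
    stop("features do not look per-image normalized (|value| > 20); ",
         "run normalize_per_image() first or set allow_unnormalized = TRUE")
  predict(object$svm, x)
}

#' Save / load a staging model as versioned JSON
#'
#' The file stores the chosen kernel and hyperparameters, the feature
#' conventions, and the full dual solution (support vectors, coefficients,
#' offset). Loading a file with a different format version fails loudly.
#'
#' @param model A `staging_model`.
#' @param path Output JSON path.
#' @export
save_staging_model <- function(model, path) {
  s <- model$svm
  obj <- list(
    format = "fuccistage-model", version = 1L,
    feature_names = model$feature_names,
    grid_point = as.list(model$grid_point),
    grid_index = model$grid_index,
    validation_score = model$validation_score, seed = model$seed,
    class_weights = as.list(model$class_weights),
    svm = list(levels = s$levels, kernel = s$kernel, C = s$C,
               gamma = s$gamma, coef0 = s$coef0, degree = s$degree,
               rho = s$rho, sv_alpha = s$sv_alpha, sv_y = s$sv_y,
               sv_x = s$sv_x, n_train = s$n_train))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_staging_model
#' @export
load_staging_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "fuccistage-model") ||
      !identical(as.integer(obj$version), 1L))
    stop("not a version-1 fuccistage model file: ", path)
  s <- obj$svm
  svm <- structure(
    list(levels = s$levels, kernel = s$kernel, C = s$C, gamma = s$gamma,
         coef0 = s$coef0, degree = as.integer(s$degree),
         class_weights = unlist(obj$class_weights),
         sv_x = matrix(as.numeric(s$sv_x), ncol = 2),
         sv_y = as.integer(s$sv_y), sv_alpha = as.numeric(s$sv_alpha),
         rho = s$rho, iterations = NA_integer_, converged = TRUE,
         n_train = s$n_train),
    class = "weighted_svm")
  structure(list(svm = svm,
                 grid_point = as.data.frame(obj$grid_point,
                                            stringsAsFactors = FALSE),
                 grid_index = obj$grid_index,
                 validation_score = obj$validation_score, seed = obj$seed,
                 feature_names = obj$feature_names,
                 class_weights = unlist(obj$class_weights)),
            class = "staging_model")
}
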