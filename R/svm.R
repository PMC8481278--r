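kernel_codes <- c(linear = 0L, rbf = 1L, poly = 2L, sigmoid = 3L)

#' Fit a binary class-weighted SVM (C-SVC)
#'
#' Dual coordinate (SMO) solver with per-sample box constraints
#' `C_i = C * w_class(i)`, supporting linear, RBF, polynomial and sigmoid
#' kernels. No SVM implementation ships with this R toolchain, so the
#' solver is built in (see `src/svm_smo.cpp`); it follows the standard
#' maximal-violating-pair scheme with stopping tolerance `tol`.
#'
#' @param x Numeric matrix (n x d) of features.
#' @param y Factor or character vector with exactly two classes.
#' @param C Cost parameter (> 0).
#' @param class_weights Named per-class multipliers on C (default both 1).
#' @param kernel One of `"linear"`, `"rbf"`, `"poly"`, `"sigmoid"`.
#' @param gamma Kernel coefficient; default `1/ncol(x)` for poly/sigmoid
#'   when not given (required for rbf).
#' @param coef0 Independent term for poly/sigmoid kernels (default 0).
#' @param degree Polynomial degree (default 3).
#' @param tol SMO stopping tolerance (default 1e-3).
#' @param max_iter Iteration cap; non-convergence yields a warning.
#' @return An object of class `weighted_svm`.
#' @export
weighted_svm <- function(x, y, C = 1, class_weights = NULL,
                         kernel = c("linear", "rbf", "poly", "sigmoid"),
                         gamma = NULL, coef0 = 0, degree = 3L,
                         tol = 1e-3, max_iter = 100000L) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  lv <- levels(y)
  if (length(lv) != 2L) stop("exactly two classes are required")
  if (min(table(y)) < 1L) stop("a class is absent from the training data")
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  if (is.null(class_weights)) class_weights <- stats::setNames(c(1, 1), lv)
  if (!all(lv %in% names(class_weights)))
    stop("class_weights must be named with the class levels")
  yi <- ifelse(y == lv[1], 1L, -1L)
  Ci <- C * unname(class_weights[as.character(y)])
  fit <- .svm_smo_train(x, as.integer(yi), as.numeric(Ci),
                        kernel_codes[[kernel]], gamma, coef0,
                        as.integer(degree), tol, as.integer(max_iter))
  if (!fit$converged)
    warning(sprintf("SMO did not converge within %d iterations", max_iter))
  sv <- fit$alpha > 0
  structure(list(levels = lv, kernel = kernel, C = C, gamma = gamma,
                 coef0 = coef0, degree = as.integer(degree),
                 class_weights = class_weights,
                 sv_x = x[sv, , drop = FALSE],
                 sv_y = yi[sv], sv_alpha = fit$alpha[sv],
                 rho = fit$rho, iterations = fit$iterations,
                 converged = fit$converged, n_train = nrow(x)),
            class = "weighted_svm")
}

#' Decision values of a fitted SVM
#' @param model A `weighted_svm`.
#' @param newdata Numeric matrix of points to score.
#' @return Signed decision values; positive means the first class level.
#' @export
svm_decision <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (nrow(newdata) == 0L) return(numeric(0))
  if (nrow(model$sv_x) == 0L) return(rep(-model$rho, nrow(newdata)))
  .svm_smo_decision(model$sv_x, as.integer(model$sv_y),
                    as.numeric(model$sv_alpha), model$rho,
                    kernel_codes[[model$kernel]], model$gamma, model$coef0,
                    model$degree, newdata)
}

#' @export
predict.weighted_svm <- function(object, newdata, ...) {
  d <- svm_decision(object, newdata)
  factor(ifelse(d > 0, object$levels[1], object$levels[2]),
         levels = object$levels)
}

#' @export
print.weighted_svm <- function(x, ...) {
  cat(sprintf(
    "<weighted_svm: %s kernel, C=%g, %d SVs of %d, %s>\n",
    x$kernel, x$C, length(x$sv_alpha), x$n_train,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
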