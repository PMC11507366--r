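#' SVM configuration
#'
#' Kernel and hyperparameters for the classifier stage. `epsilon` is carried
#' for provenance only: the epsilon-insensitive band belongs to the regression
#' variant of the SVM and plays no role in soft-margin classification.
#'
#' @param kernel `"rbf"` or `"linear"`.
#' @param C Cost of margin violations, `> 0`.
#' @param gamma RBF curvature parameter, `> 0`; ignored by the linear kernel.
#' @param epsilon Recorded but unused (see above).
#' @param seed Optional integer seed recorded with the configuration.
#' @return A list of class `"svm_config"`.
#' @export
svm_config <- function(kernel = c("rbf", "linear"), C = 1, gamma = 0.1,
                       epsilon = 0.1, seed = NULL) {
  kernel <- match.arg(kernel)
  assert_scalar_number(C, "C")
  if (C <= 0) stop_ls("`C` must be positive", class = "lactospec_argument_error")
  assert_scalar_number(gamma, "gamma")
  if (gamma <= 0) stop_ls("`gamma` must be positive",
                          class = "lactospec_argument_error")
  structure(list(kernel = kernel, C = C, gamma = gamma, epsilon = epsilon,
                 seed = seed), class = "svm_config")
}

#' Train a soft-margin SVM on cluster-component scores
#'
#' Fits a multi-class SVM (one-vs-one voting, libsvm) with the given kernel
#' and parameters. Features are centered and scaled to the training
#' statistics before fitting, so the gamma range is comparable across
#' datasets. Class levels follow the canonical [milk_classes()] order where
#' applicable; ties in the vote resolve toward the first class in that order.
#'
#' @param scores Numeric n x k matrix of cluster-component scores.
#' @param labels Class labels, at least two distinct values.
#' @param config An [svm_config()].
#' @return An object of class `"svm_fit"` wrapping the fitted machinery, the
#'   configuration and the training class levels.
#' @export
fit_svm <- function(scores, labels, config = svm_config()) {
  scores <- as.matrix(scores)
  if (anyNA(scores) || any(!is.finite(scores)))
    stop_ls("scores contain missing or non-finite values",
            class = "lactospec_validation_error")
  y <- canonical_factor(labels)
  if (nlevels(y) < 2L)
    stop_ls("training labels contain a single class (`", levels(y), "`); ",
            "at least two are required", class = "lactospec_argument_error")
  fit <- e1071::svm(x = scores, y = y,
                    kernel = if (config$kernel == "rbf") "radial" else "linear",
                    cost = config$C, gamma = config$gamma,
                    scale = rep(TRUE, ncol(scores)), type = "C-classification")
  structure(list(fit = fit, config = config, classes = levels(y), k = ncol(scores)),
            class = "svm_fit")
}

canonical_factor <- function(labels) {
  labels <- as.character(labels)
  canon <- milk_classes()
  lev <- if (all(labels %in% canon)) canon[canon %in% labels]
         else sort(unique(labels))
  factor(labels, levels = lev)
}

#' @export
predict.svm_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$k)
    stop_ls("newdata has ", ncol(newdata), " columns; the model was trained on ",
            object$k, class = "lactospec_shape_error")
  p <- stats::predict(object$fit, newdata)
  factor(as.character(p), levels = object$classes)
}

#' @export
print.svm_fit <- function(x, ...) {
  cat("<svm_fit> ", x$config$kernel, " kernel, C = ",
      format(x$config$C, digits = 4),
      if (x$config$kernel == "rbf")
        paste0(", gamma = ", format(x$config$gamma, digits = 4)),
      "; classes: ", paste(x$classes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tune an SVM over a log-spaced hyperparameter grid
#'
#' Evaluates every configuration on a log-spaced grid over
#' `C` in `C_bounds` (and `gamma` in `gamma_bounds` for the RBF kernel),
#' including the exact bound values. Each of the `repeats` repetitions
#' shuffles the training samples with a fresh derived seed and runs 5-fold
#' cross-validation; a configuration's score is its mean CV accuracy over all
#' repetitions. The winner is the highest-scoring configuration, ties broken
#' toward smaller `C`, then smaller `gamma`; it is then refit on all training
#' rows. Selection never sees validation data.
#'
#' @param scores,labels Training cluster scores and class labels.
#' @param kernel `"rbf"` or `"linear"`.
#' @param C_bounds,gamma_bounds Positive `c(min, max)` search bounds
#'   (defaults 0.01-5 and 0.001-0.5).
#' @param n_grid Grid points per parameter (default 7).
#' @param repeats Number of re-seeded cross-validation repetitions
#'   (default 20).
#' @param folds Number of CV folds (default 5).
#' @param seed Master seed for the CV shuffles.
#' @return List of class `"svm_tuning"`: `config` (winning [svm_config()]),
#'   `model` (the refit [fit_svm()] object), and `report` (data frame with
#'   one row per configuration and its mean CV accuracy).
#' @export
tune_svm <- function(scores, labels, kernel = c("rbf", "linear"),
                     C_bounds = c(0.01, 5), gamma_bounds = c(0.001, 0.5),
                     n_grid = 7L, repeats = 20L, folds = 5L, seed = 1L) {
  kernel <- match.arg(kernel)
  if (repeats < 1L) stop_ls("`repeats` must be >= 1",
                            class = "lactospec_argument_error")
  scores <- as.matrix(scores)
  y <- canonical_factor(labels)
  n <- nrow(scores)
  C_grid <- log_spaced(C_bounds[1], C_bounds[2], n_grid)
  g_grid <- if (kernel == "rbf") log_spaced(gamma_bounds[1], gamma_bounds[2],
                                            n_grid) else NA_real_
  grid <- expand.grid(gamma = g_grid, C = C_grid,
                      KEEP.OUT.ATTRS = FALSE)[, 2:1]
  grid <- unique(grid[order(grid$C, grid$gamma), , drop = FALSE])
  rownames(grid) <- NULL
  sub_seeds <- derive_seeds(seed, repeats)
  correct <- matrix(0, nrow(grid), repeats)
  for (r in seq_len(repeats)) {
    perm <- with_seed(sub_seeds[r], sample.int(n))
    fold_of <- integer(n)
    fold_of[perm] <- rep_len(seq_len(folds), n)
    for (f in seq_len(folds)) {
      hold <- fold_of == f
      if (nlevels(droplevels(y[!hold])) < 2L) next
      for (gi in seq_len(nrow(grid))) {
        cfg <- svm_config(kernel = kernel, C = grid$C[gi],
                          gamma = if (kernel == "rbf") grid$gamma[gi] else 0.1)
        m <- fit_svm(scores[!hold, , drop = FALSE], y[!hold], cfg)
        pred <- predict(m, scores[hold, , drop = FALSE])
        correct[gi, r] <- correct[gi, r] + sum(pred == y[hold])
      }
    }
  }
  acc <- rowMeans(correct) / n
  best <- which.max(acc)   # grid ordered by (C, gamma): first max = smallest C
  win <- svm_config(kernel = kernel, C = grid$C[best],
                    gamma = if (kernel == "rbf") grid$gamma[best] else 0.1,
                    seed = seed)
  report <- cbind(grid, mean_cv_accuracy = acc)
  structure(list(config = win, model = fit_svm(scores, y, win),
                 report = report, repeats = repeats, folds = folds),
            class = "svm_tuning")
}

#' @export
print.svm_tuning <- function(x, ...) {
  cat("<svm_tuning> ", nrow(x$report), " configurations, ", x$repeats,
      " x ", x$folds, "-fold CV\n", sep = "")
  cat(sprintf("winner: %s kernel, C = %.4g%s (mean CV accuracy %.1f%%)\n",
              x$config$kernel, x$config$C,
              if (x$config$kernel == "rbf")
                sprintf(", gamma = %.4g", x$config$gamma) else "",
              100 * max(x$report$mean_cv_accuracy)))
  invisible(x)
}
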