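#' Fit a variable cluster-support vector machine (VC-SVM) hybrid model
#'
#' The core model of the package: wavelength variables of the (pre-treated)
#' training spectra are partitioned into `k` clusters, each summarized by the
#' first principal component of its standardized members, and the resulting
#' cluster-component scores feed a kernel SVM. With `tune = TRUE` the SVM
#' hyperparameters are selected by repeated, re-seeded 5-fold
#' cross-validation over a log-spaced grid (`C` in 0.01-5 and, for the RBF
#' kernel, `gamma` in 0.001-0.5, 20 repetitions by default); validation data
#' plays no role in fitting or selection.
#'
#' @param x Training data: a replicate-averaged, pre-treated [spectra_set()]
#'   or a numeric samples x wavelengths matrix.
#' @param labels Class labels; taken from `x$meta$label` when `x` is a
#'   spectra set and `labels` is missing.
#' @param k Number of variable clusters (default 6).
#' @param kernel `"rbf"` or `"linear"`.
#' @param tune Tune `C` (and `gamma`) by repeated cross-validation? If
#'   `FALSE`, `config` is used as given.
#' @param config An [svm_config()] used when `tune = FALSE`.
#' @param C_bounds,gamma_bounds,n_grid,repeats Tuning grid settings, see
#'   [tune_svm()].
#' @param seed Master seed for the tuning shuffles.
#' @return An object of class `"vcsvm"`: list with the fitted `varclus`
#'   model, the fitted `svm` ([fit_svm()] object), the winning `config`, the
#'   `tuning` report (or `NULL`), and the training class levels.
#' @seealso [predict.vcsvm()], [run_experiment()] for the full experiment.
#' @examples
#' \donttest{
#' cfg <- synthetic_config(n_per_class = c(whole = 6, no_class = 6,
#'                                         semi_skimmed = 6, skimmed = 6),
#'                         replicates = 3)
#' s <- preprocess(average_replicates(simulate_milk_spectra(cfg, seed = 7)),
#'                 "snv")
#' fit <- vcsvm(s, k = 4, kernel = "rbf", tune = FALSE,
#'              config = svm_config("rbf", C = 5, gamma = 0.1))
#' table(predict(fit, s), s$meta$label)
#' }
#' @export
vcsvm <- function(x, labels = NULL, k = 6L, kernel = c("rbf", "linear"),
                  tune = TRUE, config = NULL,
                  C_bounds = c(0.01, 5), gamma_bounds = c(0.001, 0.5),
                  n_grid = 7L, repeats = 20L, seed = 1L) {
  kernel <- match.arg(kernel)
  if (inherits(x, "spectra_set")) {
    if (is.null(labels)) labels <- x$meta$label
    mat <- x$absorbance
  } else mat <- as.matrix(x)
  if (is.null(labels))
    stop_ls("`labels` missing and not present in the spectra metadata",
            class = "lactospec_argument_error")
  vc <- varclus(mat, k = k)
  scores <- predict(vc, mat)
  if (tune) {
    tuning <- tune_svm(scores, labels, kernel = kernel, C_bounds = C_bounds,
                       gamma_bounds = gamma_bounds, n_grid = n_grid,
                       repeats = repeats, seed = seed)
    svm_fit <- tuning$model
    config <- tuning$config
  } else {
    if (is.null(config)) config <- svm_config(kernel = kernel)
    if (config$kernel != kernel)
      stop_ls("`config` kernel disagrees with `kernel`",
              class = "lactospec_argument_error")
    tuning <- NULL
    svm_fit <- fit_svm(scores, labels, config)
  }
  structure(list(varclus = vc, svm = svm_fit, config = config,
                 tuning = tuning, classes = svm_fit$classes,
                 call = match.call()),
            class = "vcsvm")
}

#' Predict milk classes from a fitted VC-SVM model
#'
#' @param object A fitted [vcsvm()] model.
#' @param newdata A [spectra_set()] (pre-treated the same way as the training
#'   data) or a matrix on the training wavelength grid.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.vcsvm <- function(object, newdata, ...) {
  mat <- if (inherits(newdata, "spectra_set")) newdata$absorbance
         else as.matrix(newdata)
  predict(object$svm, predict(object$varclus, mat))
}

#' @export
print.vcsvm <- function(x, ...) {
  cat("VC-SVM hybrid model\n")
  cat(sprintf("  %d cluster components explaining %.1f%% of the variance\n",
              x$varclus$k, 100 * x$varclus$variance_explained))
  cat(sprintf("  %s-kernel SVM, C = %.4g%s%s\n", x$config$kernel, x$config$C,
              if (x$config$kernel == "rbf")
                sprintf(", gamma = %.4g", x$config$gamma) else "",
              if (!is.null(x$tuning)) " (tuned)" else ""))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.vcsvm <- function(object, ...) {
  list(varclus = summary(object$varclus), config = object$config,
       tuning_report = object$tuning$report)
}

#' @export
coef.vcsvm <- function(object, ...) coef(object$varclus)
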