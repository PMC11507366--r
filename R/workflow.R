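#' Configuration for a full classification experiment
#'
#' Either `synthetic` (a [synthetic_config()]) or `input` (paths
#' `list(spectra = , meta = )`) must be given, not both.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when reading files.
#' @param input `list(spectra = path, meta = path)`, or `NULL` when
#'   simulating.
#' @param method Pre-treatment method, see [preprocess()].
#' @param fraction,stratify Training split settings, see [split_spectra()].
#' @param k Number of variable clusters.
#' @param kernels Kernels to fit and compare.
#' @param C_bounds,gamma_bounds,n_grid,repeats Tuning settings, see
#'   [tune_svm()].
#' @param seed Master seed; every random stage derives its seed from it.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(synthetic = synthetic_config(), input = NULL,
                              method = "snv", fraction = 0.5, stratify = TRUE,
                              k = 6L, kernels = c("linear", "rbf"),
                              C_bounds = c(0.01, 5),
                              gamma_bounds = c(0.001, 0.5),
                              n_grid = 7L, repeats = 20L, seed = 1L) {
  if (is.null(synthetic) == is.null(input))
    stop_ls("give exactly one of `synthetic` or `input`",
            class = "lactospec_argument_error")
  stopifnot(all(kernels %in% c("linear", "rbf")))
  structure(list(synthetic = synthetic, input = input, method = method,
                 fraction = fraction, stratify = stratify, k = as.integer(k),
                 kernels = kernels, C_bounds = C_bounds,
                 gamma_bounds = gamma_bounds, n_grid = as.integer(n_grid),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the full VC-SVM classification experiment
#'
#' Executes the pipeline once per kernel: simulate (or read) spectra,
#' average the replicate scans, apply the pre-treatment, split samples
#' 50/50 into training and validation sets, fit the variable clustering on
#' the training matrix only, tune and train the SVM on training cluster
#' scores only, and evaluate confusion matrices and class-wise metrics on
#' both sets. Validation rows never influence standardization constants,
#' cluster loadings, feature scaling or model selection. The whole run is
#' reproducible from the master seed.
#'
#' @param cfg An [experiment_config()].
#' @return An object of class `"vcsvm_experiment"`: per kernel, the winning
#'   configuration and, per set (training/validation), the
#'   [confusion_matrix()], overall accuracy, and per-class
#'   [one_vs_all()] reductions with [classwise_metrics()]; plus the shared
#'   varclus variance explained, the fitted models, the splits and seeds.
#' @export
run_experiment <- function(cfg = experiment_config()) {
  stopifnot(inherits(cfg, "experiment_config"))
  seeds <- derive_seeds(cfg$seed, 2L + length(cfg$kernels))
  s <- if (!is.null(cfg$synthetic))
    simulate_milk_spectra(cfg$synthetic, seed = seeds[1])
  else
    read_spectra(cfg$input$spectra, cfg$input$meta)
  s <- average_replicates(s)
  if (is.null(s$meta$label))
    s$meta$label <- as.character(milk_class_from_fat(s$meta$fat_pct))
  s <- preprocess(s, cfg$method)
  parts <- split_spectra(s, fraction = cfg$fraction, seed = seeds[2],
                         stratify = cfg$stratify)
  train <- parts$training; valid <- parts$validation
  classes <- milk_classes()[milk_classes() %in% unique(train$meta$label)]

  evaluate <- function(model, set) {
    pred <- predict(model, set)
    cm <- confusion_matrix(set$meta$label, as.character(pred), classes)
    per_class <- lapply(stats::setNames(classes, classes), function(cl) {
      b <- one_vs_all(cm, cl)
      list(binary = b, metrics = classwise_metrics(b))
    })
    list(confusion = cm, accuracy = overall_accuracy(cm),
         per_class = per_class, n = sum(cm))
  }

  fits <- list(); results <- list()
  for (i in seq_along(cfg$kernels)) {
    kern <- cfg$kernels[i]
    fit <- vcsvm(train, k = cfg$k, kernel = kern, tune = TRUE,
                 C_bounds = cfg$C_bounds, gamma_bounds = cfg$gamma_bounds,
                 n_grid = cfg$n_grid, repeats = cfg$repeats,
                 seed = seeds[2L + i])
    fits[[kern]] <- fit
    results[[kern]] <- list(config = fit$config,
                            training = evaluate(fit, train),
                            validation = evaluate(fit, valid))
  }
  structure(list(results = results, models = fits,
                 variance_explained = fits[[1]]$varclus$variance_explained,
                 training = train, validation = valid,
                 config = cfg, seeds = seeds),
            class = "vcsvm_experiment")
}

#' @export
print.vcsvm_experiment <- function(x, ...) {
  cat("VC-SVM classification experiment\n")
  cat(sprintf("  training n = %d, validation n = %d, %d cluster components (%.1f%% variance)\n",
              nrow(x$training$absorbance), nrow(x$validation$absorbance),
              x$config$k, 100 * x$variance_explained))
  for (kern in names(x$results)) {
    r <- x$results[[kern]]
    cat(sprintf("  %s kernel: training accuracy %.1f%%, validation accuracy %.1f%%\n",
                kern, 100 * r$training$accuracy, 100 * r$validation$accuracy))
  }
  invisible(x)
}

#' Deterministic JSON report of an experiment
#'
#' Serializes confusion matrices, one-vs-all reductions, class-wise metrics,
#' winning configurations, variance explained and seeds; timestamps are
#' deliberately absent so identical runs give byte-identical reports.
#'
#' @param x A [run_experiment()] result.
#' @return A JSON string (class `json`).
#' @export
report_json <- function(x) {
  stopifnot(inherits(x, "vcsvm_experiment"))
  payload <- list(
    variance_explained = x$variance_explained,
    k = x$config$k,
    master_seed = x$config$seed,
    stage_seeds = x$seeds,
    note = paste("one-vs-all blocks use the standard reduction",
                 "(TP = diagonal, FN = rest of actual row,",
                 "FP = rest of predicted column)"),
    kernels = lapply(x$results, function(r) {
      per_set <- function(ev) list(
        n = ev$n,
        confusion = list(classes = rownames(ev$confusion),
                         counts = unclass(ev$confusion)),
        overall_accuracy = ev$accuracy,
        per_class = lapply(ev$per_class, function(pc)
          c(pc$binary[c("TP", "FN", "FP", "TN")], pc$metrics)))
      list(config = list(kernel = r$config$kernel, C = r$config$C,
                         gamma = r$config$gamma, epsilon = r$config$epsilon),
           training = per_set(r$training),
           validation = per_set(r$validation))
    }))
  jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE, pretty = TRUE)
}

#' Write the experiment report to disk
#'
#' Emits, per kernel and set, the multiclass confusion matrix, the one-vs-all
#' per-class table and the class-wise metrics table as CSV files, plus the
#' full deterministic JSON report.
#'
#' @param x A [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "vcsvm_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (kern in names(x$results)) {
    for (set in c("training", "validation")) {
      ev <- x$results[[kern]][[set]]
      p1 <- file.path(dir, sprintf("confusion_%s_%s.csv", kern, set))
      utils::write.csv(as.data.frame(unclass(ev$confusion)), p1)
      ova <- do.call(rbind, lapply(names(ev$per_class), function(cl) {
        b <- ev$per_class[[cl]]$binary
        data.frame(class = cl, TP = b$TP, FN = b$FN, FP = b$FP, TN = b$TN)
      }))
      p2 <- file.path(dir, sprintf("one_vs_all_%s_%s.csv", kern, set))
      utils::write.csv(ova, p2, row.names = FALSE)
      met <- do.call(rbind, lapply(names(ev$per_class), function(cl) {
        m <- ev$per_class[[cl]]$metrics
        data.frame(class = cl,
                   sensitivity_pct = round(100 * m$sensitivity, 1),
                   specificity_pct = round(100 * m$specificity, 1),
                   mcc = round(m$mcc, 2))
      }))
      p3 <- file.path(dir, sprintf("metrics_%s_%s.csv", kern, set))
      utils::write.csv(met, p3, row.names = FALSE)
      paths <- c(paths, p1, p2, p3)
    }
  }
  pj <- file.path(dir, "report.json")
  writeLines(report_json(x), pj)
  invisible(c(paths, pj))
}
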