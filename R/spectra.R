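#' Construct a spectra set
#'
#' A `spectra_set` couples an absorbance matrix on a shared, strictly
#' increasing wavelength grid with per-row sample/replicate metadata. It is the
#' container every pipeline stage consumes and returns.
#'
#' @param wavelengths Strictly increasing numeric vector of wavelengths (nm).
#' @param absorbance Numeric matrix, rows = scans, columns = wavelengths.
#' @param meta Data frame with one row per scan: columns `sample_id`
#'   (character), `replicate` (integer >= 1), `fat_pct` (numeric, % m/m), and
#'   optionally `carb_pct`, `protein_pct`, `label`, `origin_tags`.
#' @param wl_bounds Length-2 numeric; permitted wavelength range (nm).
#' @return An object of class `"spectra_set"`.
#' @export
spectra_set <- function(wavelengths, absorbance, meta,
                        wl_bounds = c(1350, 2558)) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (length(wavelengths) < 2L)
    stop_ls("wavelength grid needs at least 2 points",
            class = "lactospec_validation_error")
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0))
    stop_ls("wavelengths must be finite and strictly increasing",
            class = "lactospec_validation_error")
  if (any(wavelengths < wl_bounds[1]) || any(wavelengths > wl_bounds[2]))
    stop_ls(sprintf("wavelengths outside [%g, %g] nm",
                    wl_bounds[1], wl_bounds[2]),
            class = "lactospec_validation_error")
  if (ncol(absorbance) != length(wavelengths))
    stop_ls("absorbance has ", ncol(absorbance),
            " columns but the grid has ", length(wavelengths), " wavelengths",
            class = "lactospec_validation_error")
  if (anyNA(absorbance) || any(!is.finite(absorbance)))
    stop_ls("absorbance contains missing or non-finite values",
            class = "lactospec_validation_error")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != nrow(absorbance))
    stop_ls("meta has ", nrow(meta), " rows but absorbance has ",
            nrow(absorbance), class = "lactospec_validation_error")
  for (col in c("sample_id", "replicate"))
    if (is.null(meta[[col]]))
      stop_ls("meta lacks required column `", col, "`",
              class = "lactospec_validation_error")
  meta$sample_id <- as.character(meta$sample_id)
  meta$replicate <- as.integer(meta$replicate)
  if (any(!nzchar(meta$sample_id)) || anyNA(meta$sample_id))
    stop_ls("sample_id must be non-empty", class = "lactospec_validation_error")
  if (anyNA(meta$replicate) || any(meta$replicate < 1L))
    stop_ls("replicate index must be >= 1", class = "lactospec_validation_error")
  key <- paste(meta$sample_id, meta$replicate)
  if (anyDuplicated(key))
    stop_ls("duplicate (sample_id, replicate) pair: ", key[duplicated(key)][1],
            class = "lactospec_validation_error")
  if (!is.null(meta$fat_pct) && any(meta$fat_pct < 0, na.rm = TRUE))
    stop_ls("fat_pct must be non-negative", class = "lactospec_validation_error")
  dimnames(absorbance) <- list(NULL, format(wavelengths, trim = TRUE))
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 meta = meta, pretreatment = character()),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$absorbance), " scans of ",
      length(unique(x$meta$sample_id)), " samples, ",
      length(x$wavelengths), " wavelengths (",
      format(min(x$wavelengths)), "-", format(max(x$wavelengths)), " nm)\n",
      sep = "")
  if (length(x$pretreatment))
    cat("pretreatment:", paste(x$pretreatment, collapse = " -> "), "\n")
  if (!is.null(x$meta$label)) {
    tab <- table(x$meta$label[!duplicated(x$meta$sample_id)])
    cat("classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

# row subset preserving the class
subset_rows <- function(s, i) {
  out <- s
  out$absorbance <- s$absorbance[i, , drop = FALSE]
  out$meta <- s$meta[i, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' Read a wide spectra table and its sample metadata
#'
#' The spectra file is a wide CSV: first column `sample_id`, second column
#' `replicate`, remaining column headers the numeric wavelengths in nm
#' (UTF-8, "." decimal separator). The metadata CSV is keyed by `sample_id`
#' and carries at least `fat_pct`.
#'
#' @param path Path to the wide spectra CSV.
#' @param meta_path Path to the per-sample metadata CSV.
#' @param wl_bounds Permitted wavelength range, passed to [spectra_set()].
#' @return A validated [spectra_set()].
#' @seealso [write_spectra()] for the inverse.
#' @export
read_spectra <- function(path, meta_path, wl_bounds = c(1350, 2558)) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3L)
    stop_ls("spectra table needs sample_id, replicate and wavelength columns",
            class = "lactospec_parse_error")
  wl_head <- names(raw)[-(1:2)]
  wl <- suppressWarnings(as.numeric(wl_head))
  if (anyNA(wl))
    stop_ls("non-numeric wavelength header: `", wl_head[which(is.na(wl))[1]],
            "` (column ", which(is.na(wl))[1] + 2L, ")",
            class = "lactospec_parse_error")
  mat <- as.matrix(raw[, -(1:2), drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(raw[-(1:2)], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(raw[[bad + 2L]]))))[1]
    stop_ls("non-numeric absorbance value at row ", badrow,
            ", column `", wl_head[bad], "`", class = "lactospec_parse_error")
  }
  meta_tab <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  if (is.null(meta_tab$sample_id))
    stop_ls("metadata table lacks `sample_id`", class = "lactospec_parse_error")
  meta_tab$sample_id <- as.character(meta_tab$sample_id)
  ids <- as.character(raw[[1]])
  missing <- setdiff(unique(ids), meta_tab$sample_id)
  if (length(missing))
    stop_ls("no metadata for sample_id: ", paste(missing, collapse = ", "),
            class = "lactospec_key_error")
  meta <- cbind(data.frame(sample_id = ids,
                           replicate = as.integer(raw[[2]]),
                           stringsAsFactors = FALSE),
                meta_tab[match(ids, meta_tab$sample_id),
                         setdiff(names(meta_tab), "sample_id"),
                         drop = FALSE])
  rownames(meta) <- NULL
  spectra_set(wl, mat, meta, wl_bounds = wl_bounds)
}

#' Write a spectra set as a wide CSV plus metadata CSV
#'
#' Inverse of [read_spectra()]; full double precision is kept so a round trip
#' reproduces the absorbance matrix to better than 1e-12.
#'
#' @param s A [spectra_set()].
#' @param path,meta_path Output paths for the spectra and metadata CSVs.
#' @return Invisibly, `s`.
#' @export
write_spectra <- function(s, path, meta_path) {
  stopifnot(inherits(s, "spectra_set"))
  mat <- s$absorbance
  df <- data.frame(sample_id = s$meta$sample_id,
                   replicate = s$meta$replicate,
                   stringsAsFactors = FALSE)
  spec_cols <- as.data.frame(mat)
  names(spec_cols) <- format(s$wavelengths, trim = TRUE, digits = 15)
  utils::write.csv(cbind(df, spec_cols), path, row.names = FALSE, quote = FALSE)
  meta_cols <- setdiff(names(s$meta), "replicate")
  meta_unique <- s$meta[!duplicated(s$meta$sample_id), meta_cols, drop = FALSE]
  utils::write.csv(meta_unique, meta_path, row.names = FALSE, quote = FALSE)
  invisible(s)
}

#' Average replicate scans within each sample
#'
#' Collapses a spectra set to one row per sample: the arithmetic mean of the
#' sample's replicate scans, taken on raw absorbance before any pre-treatment.
#' Idempotent; `replicate` is reset to 1.
#'
#' @param s A [spectra_set()].
#' @return A [spectra_set()] with one row per `sample_id`.
#' @export
average_replicates <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  ids <- s$meta$sample_id
  uniq <- unique(ids)
  mat <- matrix(0, length(uniq), ncol(s$absorbance))
  for (i in seq_along(uniq))
    mat[i, ] <- colMeans(s$absorbance[ids == uniq[i], , drop = FALSE])
  meta <- s$meta[match(uniq, ids), , drop = FALSE]
  meta$replicate <- 1L
  rownames(meta) <- NULL
  out <- spectra_set(s$wavelengths, mat, meta)
  out$pretreatment <- s$pretreatment
  out
}

#' Split samples into training and validation sets
#'
#' Random, seed-reproducible partition of a replicate-averaged spectra set.
#' The training set receives `floor(fraction * n + 0.5)` samples, so with an
#' odd sample count and `fraction = 0.5` the extra sample goes to training
#' (73 samples split 37/36). With `stratify = TRUE` (default) each class
#' contributes to both subsets in proportion to `fraction`, up to integer
#' rounding; remainders are allocated by largest fractional part, ties broken
#' by the seeded draw.
#'
#' @param s A replicate-averaged [spectra_set()] whose metadata has a `label`
#'   column (or `fat_pct`, from which labels are derived when stratifying).
#' @param fraction Training fraction, strictly between 0 and 1.
#' @param seed Integer seed making the partition deterministic.
#' @param stratify Stratify by milk class?
#' @return `list(training = , validation = )` of two disjoint spectra sets
#'   whose union is `s`.
#' @export
split_spectra <- function(s, fraction = 0.5, seed = 1L, stratify = TRUE) {
  stopifnot(inherits(s, "spectra_set"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop_ls("`fraction` must lie strictly between 0 and 1",
            class = "lactospec_argument_error")
  if (anyDuplicated(s$meta$sample_id))
    stop_ls("split requires a replicate-averaged set (one row per sample); ",
            "call average_replicates() first",
            class = "lactospec_argument_error")
  n <- nrow(s$absorbance)
  n_train <- floor(fraction * n + 0.5)
  if (!stratify) {
    idx <- with_seed(seed, sample.int(n, n_train))
  } else {
    labels <- s$meta$label
    if (is.null(labels)) labels <- as.character(milk_class_from_fat(s$meta$fat_pct))
    labels <- as.character(labels)
    counts <- table(labels)
    if (any(counts < 2L))
      stop_ls("stratified split needs >= 2 samples per class; class `",
              names(counts)[counts < 2L][1], "` has ",
              min(counts), class = "lactospec_argument_error")
    idx <- with_seed(seed, {
      share <- fraction * counts
      base <- floor(share)
      rem <- n_train - sum(base)
      frac <- share - base
      ord <- order(-frac, stats::runif(length(frac)))
      take <- base
      if (rem > 0) take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
      unlist(lapply(names(counts), function(cl) {
        pool <- which(labels == cl)
        pool[sample.int(length(pool), take[[cl]])]
      }), use.names = FALSE)
    })
  }
  idx <- sort(idx)
  list(training = subset_rows(s, idx),
       validation = subset_rows(s, setdiff(seq_len(n), idx)))
}

#' Plot mean spectra by milk class
#'
#' Mean absorbance per class (solid line) with a plus/minus one standard
#' deviation band, the standard way raw-vs-SNV scatter reduction is shown.
#'
#' @param x A [spectra_set()].
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.spectra_set <- function(x, ...) {
  labels <- x$meta$label %||% as.character(milk_class_from_fat(x$meta$fat_pct))
  labels <- droplevels(factor(as.character(labels), levels = milk_classes()))
  cols <- c(whole = "red", no_class = "goldenrod",
            semi_skimmed = "forestgreen", skimmed = "blue")
  mu <- t(vapply(levels(labels), function(cl) {
    colMeans(x$absorbance[labels == cl, , drop = FALSE])
  }, numeric(length(x$wavelengths))))
  sd_ <- t(vapply(levels(labels), function(cl) {
    apply(x$absorbance[labels == cl, , drop = FALSE], 2, stats::sd)
  }, numeric(length(x$wavelengths))))
  graphics::matplot(x$wavelengths, t(mu), type = "l", lty = 1,
                    col = cols[levels(labels)],
                    xlab = "wavelength (nm)", ylab = "absorbance", ...)
  for (i in seq_len(nrow(mu)))
    graphics::polygon(c(x$wavelengths, rev(x$wavelengths)),
                      c(mu[i, ] - sd_[i, ], rev(mu[i, ] + sd_[i, ])),
                      border = NA,
                      col = grDevices::adjustcolor(cols[levels(labels)][i], 0.15))
  graphics::legend("topright", legend = levels(labels), lty = 1,
                   col = cols[levels(labels)], bty = "n")
  invisible(x)
}
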