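#' Standard normal variate transform
#'
#' Per-spectrum scatter correction: subtract the spectrum mean and divide by
#' its sample standard deviation (n - 1 denominator). The result has mean 0
#' and standard deviation 1, and is invariant to any positive affine transform
#' `a * x + b` of the input — which is exactly how multiplicative scatter and
#' additive offset artifacts enter a reflectance measurement.
#'
#' @param x Numeric vector (one spectrum), length >= 2, not constant.
#' @return The standardized spectrum.
#' @examples
#' snv(c(1, 2, 3))  # -1 0 1
#' @export
snv <- function(x) {
  if (!is.numeric(x) || length(x) < 2L)
    stop_ls("`x` must be a numeric vector of length >= 2",
            class = "lactospec_argument_error")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop_ls("SNV is undefined for a constant spectrum (sd = 0)",
            class = "lactospec_degenerate_error")
  (x - mean(x)) / s
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Sliding-window least-squares polynomial filter. Derivatives are returned in
#' physical units: absorbance per nm (`deriv = 1`) or per nm^2 (`deriv = 2`),
#' using the grid spacing. The grid must be uniform (relative tolerance 1e-6);
#' interpolate non-uniform spectra first. Edges are handled by mirror padding
#' so the output has the same length as the input.
#'
#' @param x Numeric spectrum, length >= `window`.
#' @param wavelengths The wavelength grid (nm), equally spaced.
#' @param window Odd filter width >= 5.
#' @param polyorder Polynomial degree, `>= 1` and `< window`.
#' @param deriv Derivative order, 0, 1 or 2; at most `polyorder`.
#' @return Filtered spectrum, same length as `x`.
#' @export
savgol <- function(x, wavelengths, window = 11L, polyorder = 2L, deriv = 0L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  deriv <- as.integer(deriv)
  if (window < 5L || window %% 2L == 0L)
    stop_ls("`window` must be an odd integer >= 5",
            class = "lactospec_argument_error")
  if (polyorder < 1L || polyorder >= window)
    stop_ls("`polyorder` must satisfy 1 <= polyorder < window",
            class = "lactospec_argument_error")
  if (deriv < 0L || deriv > 2L || deriv > polyorder)
    stop_ls("`deriv` must be in {0, 1, 2} and <= polyorder",
            class = "lactospec_argument_error")
  if (length(x) != length(wavelengths))
    stop_ls("spectrum and grid lengths differ",
            class = "lactospec_argument_error")
  if (window >= length(x))
    stop_ls("`window` (", window, ") must be smaller than the spectrum length (",
            length(x), ")", class = "lactospec_argument_error")
  d <- diff(wavelengths)
  h <- mean(d)
  if (any(abs(d - h) > 1e-6 * abs(h)))
    stop_ls("Savitzky-Golay requires an equally spaced wavelength grid; ",
            "interpolate the spectra onto a uniform grid first",
            class = "lactospec_argument_error")
  half <- (window - 1L) %/% 2L
  # central row of the least-squares filter matrix = convolution kernel
  kern <- unclass(signal::sgolay(p = polyorder, n = window, m = deriv))[half + 1L, ]
  L <- length(x)
  padded <- c(x[(half + 1L):2L], x, x[(L - 1L):(L - half)])
  out <- vapply(seq_len(L),
                function(i) sum(kern * padded[i:(i + window - 1L)]),
                numeric(1))
  out / h^deriv
}

#' Apply a pre-treatment to every spectrum of a set
#'
#' Row-wise application of the pre-treatments evaluated for milk spectra:
#' standard normal variate (the method retained for the classification
#' pipeline), Savitzky-Golay first or second derivative, or SNV followed by a
#' Savitzky-Golay derivative. Metadata is untouched; the method is appended to
#' the set's `pretreatment` provenance record.
#'
#' @param s A [spectra_set()].
#' @param method One of `"none"`, `"snv"`, `"sg1"`, `"sg2"`, `"snv_sg"`.
#' @param window,polyorder Savitzky-Golay parameters (defaults 11 and 2).
#' @param deriv Derivative order for `method = "snv_sg"` (default 1).
#' @return The pre-treated [spectra_set()].
#' @export
preprocess <- function(s, method = c("none", "snv", "sg1", "sg2", "snv_sg"),
                       window = 11L, polyorder = 2L, deriv = 1L) {
  stopifnot(inherits(s, "spectra_set"))
  method <- match.arg(method)
  if (method == "none") return(s)
  mat <- s$absorbance
  apply_row <- function(i, fun) {
    tryCatch(fun(mat[i, ]), error = function(e) {
      stop_ls("pre-treatment `", method, "` failed for sample `",
              s$meta$sample_id[i], "` (replicate ", s$meta$replicate[i],
              "): ", conditionMessage(e), class = "lactospec_validation_error")
    })
  }
  out <- mat
  for (i in seq_len(nrow(mat))) {
    out[i, ] <- switch(method,
      snv = apply_row(i, snv),
      sg1 = apply_row(i, function(v) savgol(v, s$wavelengths, window, polyorder, 1L)),
      sg2 = apply_row(i, function(v) savgol(v, s$wavelengths, window, polyorder, 2L)),
      snv_sg = apply_row(i, function(v)
        savgol(snv(v), s$wavelengths, window, polyorder, deriv)))
  }
  s$absorbance <- out
  s$pretreatment <- c(s$pretreatment, method)
  s
}
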