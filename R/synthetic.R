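#' Configuration for the synthetic milk NIR spectra generator
#'
#' Defines a UHT cow-milk dataset emulating the study conditions of the
#' classification experiment: 73 samples (whole 19, no-class 9, semi-skimmed
#' 34, skimmed 11) with fat contents drawn from the per-class label statistics
#' (mean +/- sd: whole 3.71 +/- 0.35, no-class 0.98 +/- 0.12, semi-skimmed
#' 1.59 +/- 0.04, skimmed 0.17 +/- 0.18 % m/m), 20 replicate scans per sample
#' on a 1350-2558 nm grid with 8 nm spacing (152 points).
#'
#' Each clean spectrum is a constant baseline plus Gaussian absorption bands:
#' dominant water bands at 1450 and 1940 nm of fixed amplitude, and weak
#' constituent bands whose amplitudes are proportional to the sample's fat,
#' protein and lactose concentrations (fat 1730/1765/2310 nm, protein
#' 2055/2180 nm, lactose 2100 nm — conventional NIR overtone/combination
#' assignments). Constituent contributions stay more than tenfold below the
#' water peak at 1450 nm. Each replicate scan is corrupted by multiplicative
#' scatter, an additive offset, a linear baseline tilt and white noise.
#'
#' @param n_per_class Named integer vector of samples per class.
#' @param fat_stats Named list of `c(mean, sd)` fat statistics per class
#'   (% m/m); draws are truncated to the class's regulatory fat interval so
#'   the generating class always equals [milk_class_from_fat()] of the draw.
#' @param carb_stats,protein_stats `c(mean, sd)` for carbohydrate and protein
#'   (% m/m), identical across classes.
#' @param replicates Scans per sample (default 20).
#' @param grid `c(start, stop, step)` wavelength grid in nm.
#' @param bands Data frame with columns `center`, `width`, `amp`,
#'   `constituent`; for `water` the amplitude is absolute absorbance, for
#'   other constituents it is absorbance per % m/m of that constituent.
#' @param artifacts Named vector: `mult_sd` (multiplicative scatter),
#'   `add_sd` (additive offset, absorbance), `tilt_sd` (linear tilt,
#'   absorbance per nm), `noise_sd` (white noise per point, absorbance).
#' @param baseline Constant absorbance offset of the clean spectrum.
#' @param thresholds [milk_thresholds()] used for truncation intervals.
#' @param seed Default seed used by [simulate_milk_spectra()].
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(
    n_per_class = c(whole = 19L, no_class = 9L, semi_skimmed = 34L,
                    skimmed = 11L),
    fat_stats = list(whole = c(3.71, 0.35), no_class = c(0.98, 0.12),
                     semi_skimmed = c(1.59, 0.04), skimmed = c(0.17, 0.18)),
    carb_stats = c(4.95, 0.15),
    protein_stats = c(3.35, 0.25),
    replicates = 20L,
    grid = c(start = 1350, stop = 2558, step = 8),
    bands = default_bands(),
    artifacts = c(mult_sd = 0.05, add_sd = 0.02, tilt_sd = 5e-6,
                  noise_sd = 0.001),
    baseline = 0.25,
    thresholds = milk_thresholds(),
    seed = 1L) {
  stopifnot(all(names(n_per_class) %in% milk_classes()),
            all(n_per_class >= 0), sum(n_per_class) > 0)
  if (replicates < 1L)
    stop_ls("`replicates` must be >= 1", class = "lactospec_argument_error")
  if (grid[["step"]] <= 0)
    stop_ls("grid step must be positive", class = "lactospec_argument_error")
  if (any(artifacts < 0))
    stop_ls("artifact standard deviations must be >= 0",
            class = "lactospec_argument_error")
  bands <- as.data.frame(bands)
  stopifnot(all(c("center", "width", "amp", "constituent") %in% names(bands)))
  if (!any(bands$constituent == "water"))
    stop_ls("the band model must contain a water band",
            class = "lactospec_argument_error")
  for (cl in names(fat_stats)) {
    iv <- class_fat_interval(cl, thresholds)
    if (iv[2] <= iv[1])
      stop_ls("class `", cl, "` has a zero-width fat interval",
              class = "lactospec_argument_error")
  }
  structure(list(n_per_class = n_per_class, fat_stats = fat_stats,
                 carb_stats = carb_stats, protein_stats = protein_stats,
                 replicates = as.integer(replicates), grid = grid,
                 bands = bands, artifacts = artifacts, baseline = baseline,
                 thresholds = thresholds, seed = seed),
            class = "synthetic_config")
}

#' Default NIR band model for milk
#'
#' @return Data frame of Gaussian band parameters; see [synthetic_config()].
#' @export
default_bands <- function() {
  data.frame(
    center = c(1450, 1940, 1730, 1765, 2310, 2055, 2180, 2100),
    width  = c(  55,   70,   20,   20,   25,   30,   30,   35),
    amp    = c(1.00, 0.55, 0.018, 0.014, 0.020, 0.008, 0.008, 0.006),
    constituent = c("water", "water", "fat", "fat", "fat",
                    "protein", "protein", "lactose"),
    stringsAsFactors = FALSE)
}

#' Draw per-sample compositions for a synthetic dataset
#'
#' Fat is drawn per class from a normal with the class's label statistics,
#' truncated by rejection to the class's regulatory interval (and to `>= 0`),
#' so the generated label always matches the generating class. Carbohydrate
#' and protein are drawn with no class dependence.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed (defaults to the config's).
#' @return Data frame with columns `sample_id`, `label`, `fat_pct`,
#'   `carb_pct`, `protein_pct`; one row per sample.
#' @export
sample_compositions <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(seed, {
    rows <- lapply(names(cfg$n_per_class), function(cl) {
      n <- cfg$n_per_class[[cl]]
      if (n == 0L) return(NULL)
      st <- cfg$fat_stats[[cl]]
      iv <- class_fat_interval(cl, cfg$thresholds)
      fat <- vapply(seq_len(n), function(i) {
        repeat {
          f <- stats::rnorm(1, st[1], st[2])
          if (f >= 0 && f >= iv[1] && f <= iv[2] &&
              as.character(milk_class_from_fat(f, cfg$thresholds)) == cl)
            return(f)
        }
      }, numeric(1))
      data.frame(label = cl, fat_pct = fat,
                 carb_pct = stats::rnorm(n, cfg$carb_stats[1], cfg$carb_stats[2]),
                 protein_pct = stats::rnorm(n, cfg$protein_stats[1],
                                            cfg$protein_stats[2]),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$sample_id <- sprintf("S%03d", seq_len(nrow(out)))
    out[, c("sample_id", "label", "fat_pct", "carb_pct", "protein_pct")]
  })
}

#' Clean (artifact-free) spectrum for one sample
#'
#' Sum of the baseline and the Gaussian bands of the configuration, with
#' constituent band amplitudes scaled by the sample's composition.
#'
#' @param meta One-row data frame (or list) with `fat_pct`, `carb_pct`,
#'   `protein_pct`.
#' @param cfg A [synthetic_config()].
#' @return Numeric absorbance vector on the configured grid.
#' @export
clean_spectrum <- function(meta, cfg) {
  wl <- grid_wavelengths(cfg)
  conc <- c(water = 1, fat = meta$fat_pct, protein = meta$protein_pct,
            lactose = meta$carb_pct)
  out <- rep(cfg$baseline, length(wl))
  for (b in seq_len(nrow(cfg$bands))) {
    band <- cfg$bands[b, ]
    scale <- conc[[band$constituent]]
    if (is.null(scale) || is.na(scale))
      stop_ls("composition value missing for constituent `",
              band$constituent, "`", class = "lactospec_argument_error")
    out <- out + band$amp * scale * exp(-0.5 * ((wl - band$center) / band$width)^2)
  }
  out
}

grid_wavelengths <- function(cfg) {
  seq(cfg$grid[["start"]], cfg$grid[["stop"]], by = cfg$grid[["step"]])
}

#' One corrupted replicate scan
#'
#' Applies the per-scan artifact model to a clean spectrum: multiplication by
#' `(1 + m)`, an additive offset, a linear tilt about the grid midpoint, and
#' i.i.d. Gaussian noise.
#'
#' @param meta Sample composition (see [clean_spectrum()]).
#' @param cfg A [synthetic_config()].
#' @param replicate_seed Integer seed for this scan's artifact draws.
#' @return Numeric absorbance vector.
#' @export
generate_spectrum <- function(meta, cfg, replicate_seed = 1L) {
  clean <- clean_spectrum(meta, cfg)
  wl <- grid_wavelengths(cfg)
  a <- cfg$artifacts
  with_seed(replicate_seed, {
    m <- stats::rnorm(1, 0, a[["mult_sd"]])
    b <- stats::rnorm(1, 0, a[["add_sd"]])
    t <- stats::rnorm(1, 0, a[["tilt_sd"]])
    noise <- stats::rnorm(length(wl), 0, a[["noise_sd"]])
    clean * (1 + m) + b + t * (wl - mean(range(wl))) + noise
  })
}

#' Simulate a full synthetic milk-spectra dataset
#'
#' Draws sample compositions, then `replicates` corrupted scans per sample on
#' the configured grid. Bit-identical for a given seed; round-trips through
#' [write_spectra()] / [read_spectra()].
#'
#' @param cfg A [synthetic_config()].
#' @param seed Master seed (defaults to the config's).
#' @return A [spectra_set()] with `n_samples * replicates` rows and metadata
#'   columns `sample_id`, `replicate`, `fat_pct`, `carb_pct`, `protein_pct`,
#'   `label`.
#' @export
simulate_milk_spectra <- function(cfg = synthetic_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  seeds <- derive_seeds(seed, 2L)
  comp <- sample_compositions(cfg, seed = seeds[1])
  wl <- grid_wavelengths(cfg)
  n_s <- nrow(comp); reps <- cfg$replicates
  rep_seeds <- derive_seeds(seeds[2], n_s * reps)
  mat <- matrix(0, n_s * reps, length(wl))
  meta <- data.frame(sample_id = rep(comp$sample_id, each = reps),
                     replicate = rep(seq_len(reps), times = n_s),
                     fat_pct = rep(comp$fat_pct, each = reps),
                     carb_pct = rep(comp$carb_pct, each = reps),
                     protein_pct = rep(comp$protein_pct, each = reps),
                     label = rep(comp$label, each = reps),
                     stringsAsFactors = FALSE)
  row <- 0L
  for (i in seq_len(n_s)) {
    for (r in seq_len(reps)) {
      row <- row + 1L
      mat[row, ] <- generate_spectrum(comp[i, ], cfg, rep_seeds[row])
    }
  }
  spectra_set(wl, mat, meta)
}
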