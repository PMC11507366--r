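test_that("SNV centers and scales with the sample sd", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(60, mean = runif(1, 0, 2), sd = runif(1, 0.1, 3))
    y <- snv(x)
    expect_lt(abs(mean(y)), 1e-10)
    expect_lt(abs(sd(y) - 1), 1e-10)
  }
})

test_that("SNV is idempotent and affine-invariant", {
  set.seed(12)
  x <- rnorm(80)
  expect_equal(snv(snv(x)), snv(x), tolerance = 1e-12)
  a <- 2.7; b <- -0.4
  expect_lt(max(abs(snv(a * x + b) - snv(x))), 1e-10)
})

test_that("SNV rejects constant spectra instead of returning NaN", {
  expect_error(snv(rep(1, 10)), class = "lactospec_degenerate_error")
  expect_error(snv(3), class = "lactospec_argument_error")
})

test_that("Savitzky-Golay derivatives are exact on polynomials in nm units", {
  wl <- seq(1350, by = 8, length.out = 60)
  lin <- 0.01 * wl
  d1 <- savgol(lin, wl, window = 7, polyorder = 2, deriv = 1)
  expect_equal(d1[4:57], rep(0.01, 54), tolerance = 1e-10)
  a <- 3e-5
  quad <- a * wl^2
  d2 <- savgol(quad, wl, window = 9, polyorder = 3, deriv = 2)
  expect_equal(d2[5:56], rep(2 * a, 52), tolerance = 1e-8)
  # smoothing reproduces a polynomial of degree <= polyorder exactly
  cub <- 1e-7 * wl^3 - 2e-4 * wl
  sm <- savgol(cub, wl, window = 11, polyorder = 3, deriv = 0)
  expect_equal(sm[6:55], cub[6:55], tolerance = 1e-8)
})

test_that("SG smoothing equals an independent sliding local polyfit", {
  set.seed(21)
  wl <- seq(1400, by = 8, length.out = 50)
  x <- cumsum(rnorm(50, sd = 0.05))
  window <- 9L; half <- 4L; polyorder <- 3L
  sm <- savgol(x, wl, window = window, polyorder = polyorder, deriv = 0)
  # brute-force oracle: least-squares polynomial over each interior window,
  # evaluated at the window center
  for (i in (half + 1L):(50L - half)) {
    idx <- (i - half):(i + half)
    fit <- lm(y ~ poly(t, polyorder, raw = TRUE),
              data = data.frame(y = x[idx], t = seq(-half, half)))
    expect_equal(sm[i], unname(predict(fit)[half + 1L]), tolerance = 1e-8)
  }
  # first derivative oracle on the same windows, converted to per-nm
  d1 <- savgol(x, wl, window = window, polyorder = polyorder, deriv = 1)
  for (i in c(6L, 20L, 40L)) {
    idx <- (i - half):(i + half)
    fit <- lm(y ~ poly(t, polyorder, raw = TRUE),
              data = data.frame(y = x[idx], t = seq(-half, half)))
    expect_equal(d1[i], unname(coef(fit)[2]) / 8, tolerance = 1e-8)
  }
})

test_that("SG validates grid uniformity and window arguments", {
  wl <- c(seq(1350, by = 8, length.out = 20), 1520)
  expect_error(savgol(rnorm(21), wl, 7, 2, 1),
               class = "lactospec_argument_error")
  wl <- seq(1350, by = 8, length.out = 10)
  expect_error(savgol(rnorm(10), wl, window = 11, polyorder = 2),
               class = "lactospec_argument_error")
  expect_error(savgol(rnorm(10), wl, window = 6, polyorder = 2),
               class = "lactospec_argument_error")
  expect_error(savgol(rnorm(10), wl, window = 7, polyorder = 2, deriv = 3),
               class = "lactospec_argument_error")
})

test_that("preprocess applies the method row-wise and records provenance", {
  s <- average_replicates(simulate_milk_spectra(tiny_synth_config(), seed = 3L))
  expect_identical(preprocess(s, "none"), s)
  sn <- preprocess(s, "snv")
  expect_equal(unname(rowMeans(sn$absorbance)),
               rep(0, nrow(sn$absorbance)), tolerance = 1e-10)
  expect_equal(unname(apply(sn$absorbance, 1, sd)),
               rep(1, nrow(sn$absorbance)), tolerance = 1e-10)
  expect_identical(sn$meta, s$meta)
  expect_equal(sn$pretreatment, "snv")
  sg <- preprocess(s, "sg1")
  expect_equal(dim(sg), dim(s))
  expect_true(all(is.finite(sg$absorbance)))
  both <- preprocess(s, "snv_sg")
  expect_true(all(is.finite(both$absorbance)))
})

test_that("preprocess attaches the offending sample to row-level failures", {
  meta <- data.frame(sample_id = c("ok", "flat"), replicate = c(1L, 1L),
                     fat_pct = c(1, 1))
  mat <- rbind(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8),
               rep(0.2, 8))
  s <- spectra_set(seq(1350, by = 8, length.out = 8), mat, meta)
  expect_error(preprocess(s, "snv"), regexp = "flat",
               class = "lactospec_validation_error")
})

test_that("SNV shrinks between-replicate dispersion under scatter", {
  cfg <- tiny_synth_config()
  s <- simulate_milk_spectra(cfg, seed = 8L)
  sn <- preprocess(s, "snv")
  for (id in unique(s$meta$sample_id)[1:5]) {
    rows <- s$meta$sample_id == id
    raw_disp <- mean(apply(s$absorbance[rows, ], 2, sd))
    snv_disp <- mean(apply(sn$absorbance[rows, ], 2, sd))
    expect_lt(snv_disp, raw_disp)
  }
})
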