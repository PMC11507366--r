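make_small_set <- function() {
  meta <- data.frame(sample_id = rep(c("a", "b"), each = 3),
                     replicate = rep(1:3, 2),
                     fat_pct = rep(c(3.7, 0.2), each = 3),
                     stringsAsFactors = FALSE)
  mat <- matrix(seq(0.1, 0.1 + 0.01 * 29, by = 0.01), nrow = 6)
  spectra_set(c(1350, 1358, 1366, 1374, 1382), mat, meta)
}

test_that("constructor validates grid, matrix and metadata", {
  s <- make_small_set()
  expect_s3_class(s, "spectra_set")
  expect_equal(dim(s), c(6L, 5L))
  expect_error(spectra_set(c(1366, 1358, 1350), matrix(1, 2, 3),
                           data.frame(sample_id = c("a", "b"),
                                      replicate = 1:2)),
               class = "lactospec_validation_error")
  expect_error(spectra_set(c(1350, 1358, 9999), matrix(1, 2, 3),
                           data.frame(sample_id = c("a", "b"),
                                      replicate = 1:2)),
               class = "lactospec_validation_error")
  m <- matrix(1, 2, 3); m[1, 2] <- NA
  expect_error(spectra_set(c(1350, 1358, 1366), m,
                           data.frame(sample_id = c("a", "b"),
                                      replicate = 1:2)),
               class = "lactospec_validation_error")
  expect_error(spectra_set(c(1350, 1358, 1366), matrix(1, 2, 3),
                           data.frame(sample_id = c("a", "a"),
                                      replicate = c(1L, 1L))),
               class = "lactospec_validation_error")
})

test_that("a 3-wavelength wide CSV parses into a 3-column set", {
  sp <- tempfile(fileext = ".csv"); mp <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,replicate,1350,1358,1366",
               "a,1,0.1,0.2,0.3",
               "a,2,0.1,0.2,0.3",
               "b,1,0.4,0.5,0.6"), sp)
  writeLines(c("sample_id,fat_pct", "a,3.7", "b,0.2"), mp)
  s <- read_spectra(sp, mp)
  expect_equal(dim(s), c(3L, 3L))
  expect_equal(s$wavelengths, c(1350, 1358, 1366))
  expect_equal(s$meta$fat_pct, c(3.7, 3.7, 0.2))
})

test_that("shuffled wavelength headers and missing metadata are rejected", {
  sp <- tempfile(fileext = ".csv"); mp <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,replicate,1358,1350,1366", "a,1,0.1,0.2,0.3"), sp)
  writeLines(c("sample_id,fat_pct", "a,3.7"), mp)
  expect_error(read_spectra(sp, mp), class = "lactospec_validation_error")

  writeLines(c("sample_id,replicate,1350,1358,1366", "a,1,0.1,0.2,0.3",
               "zz,1,0.1,0.2,0.3"), sp)
  expect_error(read_spectra(sp, mp), class = "lactospec_key_error")

  writeLines(c("sample_id,replicate,1350,oops,1366", "a,1,0.1,0.2,0.3"), sp)
  expect_error(read_spectra(sp, mp), class = "lactospec_parse_error")
})

test_that("write/read round trip preserves values to 1e-12 and metadata", {
  s <- simulate_milk_spectra(tiny_synth_config(), seed = 5L)
  sp <- tempfile(fileext = ".csv"); mp <- tempfile(fileext = ".csv")
  write_spectra(s, sp, mp)
  s2 <- read_spectra(sp, mp)
  expect_lt(max(abs(s2$absorbance - s$absorbance)), 1e-12)
  expect_equal(s2$meta$sample_id, s$meta$sample_id)
  expect_equal(s2$meta$replicate, s$meta$replicate)
  expect_equal(s2$meta$fat_pct, s$meta$fat_pct, tolerance = 1e-12)
  expect_equal(s2$meta$label, s$meta$label)
})

test_that("replicate averaging is the arithmetic mean and is idempotent", {
  meta <- data.frame(sample_id = c("a", "a", "b"), replicate = c(1L, 2L, 1L),
                     fat_pct = c(1, 1, 2))
  mat <- rbind(c(0, 0, 0), c(2, 2, 2), c(5, 5, 5))
  s <- spectra_set(c(1350, 1400, 1450), mat, meta)
  av <- average_replicates(s)
  expect_equal(dim(av)[1], 2L)
  expect_equal(unname(av$absorbance[1, ]), c(1, 1, 1))
  expect_equal(av$meta$replicate, c(1L, 1L))
  av2 <- average_replicates(av)
  expect_equal(av2$absorbance, av$absorbance)
})

test_that("73 samples x 20 replicates average to 73 rows", {
  s <- cached("default_dataset", simulate_milk_spectra(synthetic_config(),
                                                       seed = 99L))
  expect_equal(dim(s)[1], 73L * 20L)
  av <- average_replicates(s)
  expect_equal(dim(av)[1], 73L)
})

test_that("splits are disjoint, exhaustive, sized 37/36 and seed-stable", {
  s <- average_replicates(cached("default_dataset",
                                 simulate_milk_spectra(synthetic_config(),
                                                       seed = 99L)))
  pr <- split_spectra(s, fraction = 0.5, seed = 7L, stratify = TRUE)
  expect_equal(dim(pr$training)[1], 37L)
  expect_equal(dim(pr$validation)[1], 36L)
  ids_t <- pr$training$meta$sample_id
  ids_v <- pr$validation$meta$sample_id
  expect_length(intersect(ids_t, ids_v), 0L)
  expect_setequal(c(ids_t, ids_v), s$meta$sample_id)
  pr2 <- split_spectra(s, fraction = 0.5, seed = 7L, stratify = TRUE)
  expect_identical(pr2$training$meta$sample_id, ids_t)
  # per-class proportions near 0.5
  tab_t <- table(pr$training$meta$label)
  tab_all <- table(s$meta$label)
  expect_true(all(abs(tab_t - 0.5 * tab_all[names(tab_t)]) <= 1))
})

test_that("stratified split of 2-per-class samples puts 1 of each per side", {
  meta <- data.frame(sample_id = paste0("s", 1:8), replicate = 1L,
                     fat_pct = c(4, 4.2, 1, 1.1, 1.6, 1.7, 0.1, 0.2))
  mat <- matrix(rnorm(8 * 5), 8, 5) + 1  # values irrelevant
  mat <- abs(mat)
  s <- spectra_set(seq(1350, 1382, by = 8), mat, meta)
  s$meta$label <- as.character(milk_class_from_fat(s$meta$fat_pct))
  pr <- split_spectra(s, 0.5, seed = 3L, stratify = TRUE)
  expect_equal(as.vector(sort(table(pr$training$meta$label))),
               c(1L, 1L, 1L, 1L))
  expect_equal(as.vector(sort(table(pr$validation$meta$label))),
               c(1L, 1L, 1L, 1L))
})

test_that("split argument errors are explicit", {
  s <- average_replicates(simulate_milk_spectra(tiny_synth_config(), seed = 2L))
  expect_error(split_spectra(s, fraction = 1.2, seed = 1L),
               class = "lactospec_argument_error")
  singleton <- s
  keep <- !duplicated(singleton$meta$label) |
    singleton$meta$label != "no_class"
  singleton <- lactospec:::subset_rows(singleton, which(keep))
  expect_error(split_spectra(singleton, 0.5, seed = 1L, stratify = TRUE),
               regexp = "no_class", class = "lactospec_argument_error")
})
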