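two_clouds <- function(n = 20L, gap = 4, seed = 61L) {
  lactospec:::with_seed(seed, {
    x <- rbind(matrix(rnorm(n), n / 2, 2),
               matrix(rnorm(n) + gap, n / 2, 2))
    list(x = x, y = rep(c("skimmed", "whole"), each = n / 2))
  })
}

xor_points <- function(n_per = 10L, seed = 62L) {
  lactospec:::with_seed(seed, {
    centers <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
    lab <- c("skimmed", "skimmed", "whole", "whole")
    x <- do.call(rbind, lapply(1:4, function(i)
      cbind(rnorm(n_per, centers[i, 1], 0.08),
            rnorm(n_per, centers[i, 2], 0.08))))
    list(x = x, y = rep(lab, each = n_per))
  })
}

test_that("a separable problem is fit perfectly with a linear kernel", {
  d <- two_clouds()
  m <- fit_svm(d$x, d$y, svm_config("linear", C = 1))
  expect_equal(as.character(predict(m, d$x)), d$y)
})

test_that("the RBF kernel solves XOR where the linear kernel cannot", {
  d <- xor_points()
  rbf <- fit_svm(d$x, d$y, svm_config("rbf", C = 5, gamma = 0.5))
  expect_equal(mean(as.character(predict(rbf, d$x)) == d$y), 1.0)
  lin <- fit_svm(d$x, d$y, svm_config("linear", C = 5))
  expect_lt(mean(as.character(predict(lin, d$x)) == d$y), 1.0)
})

test_that("training accuracy is non-decreasing in C on separable data", {
  d <- two_clouds()
  acc <- vapply(c(0.01, 0.1, 1, 5), function(C) {
    m <- fit_svm(d$x, d$y, svm_config("linear", C = C))
    mean(as.character(predict(m, d$x)) == d$y)
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
})

test_that("refits are deterministic and respect the canonical class order", {
  d <- two_clouds()
  probe <- as.matrix(expand.grid(seq(-2, 6, by = 1), seq(-2, 6, by = 1)))
  m1 <- fit_svm(d$x, d$y, svm_config("rbf", C = 1, gamma = 0.2))
  m2 <- fit_svm(d$x, d$y, svm_config("rbf", C = 1, gamma = 0.2))
  expect_identical(predict(m1, probe), predict(m2, probe))
  expect_equal(m1$classes, c("whole", "skimmed"))  # canonical milk order
})

test_that("single-class and non-finite inputs are explicit errors", {
  d <- two_clouds()
  expect_error(fit_svm(d$x, rep("whole", nrow(d$x)), svm_config()),
               class = "lactospec_argument_error")
  xbad <- d$x; xbad[1, 1] <- NA
  expect_error(fit_svm(xbad, d$y, svm_config()),
               class = "lactospec_validation_error")
})

test_that("permuting prediction rows permutes outputs identically", {
  d <- two_clouds()
  m <- fit_svm(d$x, d$y, svm_config("rbf", C = 1, gamma = 0.2))
  p <- predict(m, d$x)
  perm <- rev(seq_len(nrow(d$x)))
  expect_identical(predict(m, d$x[perm, ]), p[perm])
})

test_that("a constant shift of one feature is absorbed by centering", {
  d <- two_clouds()
  m1 <- fit_svm(d$x, d$y, svm_config("rbf", C = 1, gamma = 0.2))
  shifted <- d$x; shifted[, 2] <- shifted[, 2] + 100
  m2 <- fit_svm(shifted, d$y, svm_config("rbf", C = 1, gamma = 0.2))
  probe <- two_clouds(seed = 99L)$x
  probe2 <- probe; probe2[, 2] <- probe2[, 2] + 100
  expect_identical(predict(m1, probe), predict(m2, probe2))
})

test_that("a collapsed tuning grid returns that single configuration", {
  d <- two_clouds()
  tn <- tune_svm(d$x, d$y, kernel = "rbf", C_bounds = c(1, 1),
                 gamma_bounds = c(0.2, 0.2), repeats = 2, seed = 5)
  expect_equal(nrow(tn$report), 1L)
  expect_equal(tn$config$C, 1)
  expect_equal(tn$config$gamma, 0.2)
})

test_that("tuning is reproducible from the master seed and tie-breaks to small C", {
  d <- two_clouds()
  t1 <- tune_svm(d$x, d$y, kernel = "rbf", n_grid = 3, repeats = 3, seed = 17)
  t2 <- tune_svm(d$x, d$y, kernel = "rbf", n_grid = 3, repeats = 3, seed = 17)
  expect_identical(t1$config[c("kernel", "C", "gamma")],
                   t2$config[c("kernel", "C", "gamma")])
  expect_identical(t1$report, t2$report)
  # the grid includes the exact bounds
  expect_equal(min(t1$report$C), 0.01)
  expect_equal(max(t1$report$C), 5)
  expect_equal(range(t1$report$gamma), c(0.001, 0.5))
  # on easy data many configs tie at perfect CV accuracy; winner is the
  # smallest C, then smallest gamma among the best
  best <- max(t1$report$mean_cv_accuracy)
  ties <- t1$report[t1$report$mean_cv_accuracy == best, ]
  expect_equal(t1$config$C, min(ties$C))
  expect_equal(t1$config$gamma,
               min(ties$gamma[ties$C == min(ties$C)]))
  expect_error(tune_svm(d$x, d$y, C_bounds = c(-1, 5)),
               class = "lactospec_argument_error")
})
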