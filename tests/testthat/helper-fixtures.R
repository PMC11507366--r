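# shared fixtures, all generated in code under fixed seeds

# small synthetic configuration for fast pipeline tests
tiny_synth_config <- function(...) {
  synthetic_config(
    n_per_class = c(whole = 5L, no_class = 4L, semi_skimmed = 8L,
                    skimmed = 5L),
    replicates = 4L,
    ...)
}

# a seeded n x p matrix with correlated blocks (for varclus tests)
block_matrix <- function(n = 30L, blocks = c(4L, 3L, 3L), noise = 0.3,
                         seed = 421L) {
  lactospec:::with_seed(seed, {
    cols <- lapply(blocks, function(b) {
      f <- rnorm(n)
      sapply(seq_len(b), function(i) f + noise * rnorm(n))
    })
    do.call(cbind, cols)
  })
}

# published 4-class validation counts (linear kernel), class order
# whole, no_class, semi_skimmed, skimmed
published_validation_counts <- function() {
  matrix(c(10, 0, 0, 0,
            0, 2, 1, 1,
            0, 0, 17, 0,
            0, 0, 0, 5), nrow = 4, byrow = TRUE)
}

# memoized expensive objects shared between acceptance tests
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}
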