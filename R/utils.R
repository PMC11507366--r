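# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ls <- function(..., class = "lactospec_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop_ls(sprintf("`%s` must be a single finite number in [%s, %s]",
                    name, format(lower), format(upper)),
            class = "lactospec_argument_error")
  invisible(x)
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# deterministic sub-seeds below 2^31 derived from a master seed
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

log_spaced <- function(lo, hi, n) {
  if (!is.finite(lo) || !is.finite(hi) || lo <= 0 || hi < lo)
    stop_ls("grid bounds must be positive with min <= max",
            class = "lactospec_argument_error")
  if (hi == lo) return(lo)
  exp(seq(log(lo), log(hi), length.out = n))
}
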