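## Internal helpers shared across modules.

# Fan a master seed out to reproducible child seeds, one per named stage.
# Children stay below 2^31 so they are valid R integer seeds.
child_seeds <- function(seed, stages) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  out <- sample.int(.Machine$integer.max - 1L, length(stages))
  names(out) <- stages
  out
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Run an expression under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
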