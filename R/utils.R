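# Internal helpers: scoped RNG, seed splitting, small validators.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive `n` independent 31-bit sub-seeds from a master seed, so each
# generator (alignment / operon / protein) owns its own stream.
splitSeed <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  }
  invisible(x)
}

.assertFileExists <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("'path' must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  invisible(path)
}
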