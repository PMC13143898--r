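# Internal helpers shared across modules.

# Evaluate `code` under a local RNG stream started from `seed`, restoring the
# caller's .Random.seed afterwards.  All exported stochastic operations route
# their randomness through this so no call leaks global RNG state.
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and an index, staying inside the
# 32-bit signed integer range R requires of set.seed().
childSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Population (divide-by-n) moments used for feature statistics.
popSd <- function(x) sqrt(mean((x - mean(x))^2))

stopIfNot3Channel <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("expected an H x W x 3 RGB array, got dimensions [",
         paste(dim(rgb), collapse = " x "), "]")
  invisible(rgb)
}
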