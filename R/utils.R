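# Internal helpers shared across the package.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards.  All exported stochastic functions route their randomness
# through this so that no call mutates global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic derived seed for (sweep seed, candidate index, fold index)
# triples, kept inside 32-bit integer range.
derive_seed <- function(seed, candidate = 0L, fold = 0L) {
  s <- (as.double(seed) * 2654435761 + candidate * 97561 + fold * 1299721)
  as.integer(s %% 2147483587) + 1L
}

check_binary_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x)) stop(sprintf("'%s' must be a matrix", name))
  bad <- which(!(x %in% c(0, 1)))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(x))
    stop(sprintf("'%s' has a non-binary entry at row %d, column %d (value %s)",
                 name, i[1L], i[2L], format(x[bad[1L]])))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
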