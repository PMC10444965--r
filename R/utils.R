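#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Deterministic child seed from a master seed and an index, kept < 2^31 so it is
# always a valid R integer. Doubles are exact here (products < 2^53).
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(index) * 16807) %% 2147483647
  as.integer(x)
}

# Run code under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(seed)
  force(code)
}

# sample() without its size-1 surprise: sample_vec(5L, 1) never draws from 1:5.
sample_vec <- function(x, size = length(x)) {
  x[sample.int(length(x), size)]
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= min && x == trunc(x)
}
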