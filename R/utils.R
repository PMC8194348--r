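#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the previous
#' RNG state so callers' random streams are unaffected.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive per-stage seeds from a master seed
#'
#' Fans one master seed out into a named vector of independent stage seeds, so
#' that each pipeline stage has its own deterministic stream and inserting a
#' stage does not shift the others.
#'
#' @param seed Master integer seed.
#' @param stages Character vector of stage names.
#' @return Named integer vector of seeds (all below 2^31).
#' @export
fan_out_seeds <- function(seed, stages) {
  stopifnot(length(stages) >= 1)
  s <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(stages)))
  stats::setNames(s, stages)
}

# adjacent letter pairs of a string (length n-1)
letter_bigrams <- function(x) {
  n <- nchar(x)
  if (n < 2) return(character(0))
  substring(x, 1:(n - 1), 2:n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
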