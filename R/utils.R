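#' Evaluate code with a temporary RNG seed
#'
#' Runs \code{code} with the random-number generator seeded at \code{seed},
#' restoring the caller's RNG state afterwards so library calls never perturb
#' a user's simulation stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a stream of sub-seeds from one master seed
#'
#' All randomness in the package flows from a single user-visible seed; each
#' independent component (subject, fold) receives its own sub-seed drawn from
#' the seeded stream, so components are reproducible individually and jointly.
#'
#' @param seed master seed.
#' @param n number of sub-seeds.
#' @return integer vector of length \code{n}, each in [1, 2^31 - 2].
#' @keywords internal
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# single consistent stop() wrapper so stage names show up in messages
stop2 <- function(...) stop(..., call. = FALSE)
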