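#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded package internals
#' do not disturb the caller's random number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  expr
}

#' Derive child seeds from a master seed
#'
#' Hierarchical seeding (master -> resample -> fold) so that any single
#' stage is reproducible in isolation. Seeds stay below 2^31 - 1.
#'
#' @param seed master seed.
#' @param n number of child seeds.
#' @return integer vector of length \code{n}.
#' @keywords internal
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# clip to a closed interval
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# informative stop() with sprintf semantics
abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
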