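# Internal helpers: seeding and argument checks.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers' random streams are unaffected.
#' @noRd
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
  code
}

#' Derive n child seeds from one top-level seed
#'
#' All stochastic components (per-forest seeds, permutation streams,
#' half-splits) draw their seeds through this so that a single integer
#' reproduces an entire analysis. Values stay below 2^31 - 1.
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' @noRd
check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %s", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %s", name, lower), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %s", name, upper), call. = FALSE)
  }
  invisible(x)
}

#' @noRd
check_count <- function(x, name, lower = 1L) {
  check_scalar_number(x, name, lower = lower)
  if (x != as.integer(x)) {
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  }
  as.integer(x)
}
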