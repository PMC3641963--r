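#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so seeded generators do not disturb user randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# Derive a reproducible sub-seed for a named module stream from a root seed.
# Keeps results < 2^31 so set.seed() accepts them.
sub_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_len(nchar(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

# Shared argument checks ------------------------------------------------

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 &&
    (if (open_upper) x < 1 else x <= 1)
  if (!ok) {
    stop(sprintf("'%s' must be a fraction in [0, %s", name,
                 if (open_upper) "1)" else "1]"), call. = FALSE)
  }
  invisible(as.numeric(x))
}
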