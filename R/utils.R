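# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs `expr`, then restores the caller's RNG state so that
#' seeded generators are pure functions of their arguments and never disturb
#' the session stream.
#' @noRd
with_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed))
  expr
}

# deterministic child seeds for replicate loops; kept well below 2^31
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "icpbin_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  length(x) > 0L && all(x %in% c(0, 1))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# canonical label for a predictor subset (empty set included)
subset_key <- function(subset) {
  if (length(subset) == 0L) "(empty)" else paste(subset, collapse = "+")
}
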