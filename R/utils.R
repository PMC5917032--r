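#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so that library functions never disturb the global random
#' stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic child seeds: one stream per (stage, unit), all descending
## from a single master seed. Documented splitting scheme: a linear
## congruential hash of (master, stage index, unit index) folded into the
## 31-bit integer range.
child_seed <- function(master, stage, unit = 0L) {
  stages <- c(simulate = 1L, inputs = 2L, cjs = 3L, bootstrap = 4L,
              ltre = 5L, care = 6L, misc = 7L)
  s <- if (is.character(stage)) stages[[stage]] else as.integer(stage)
  x <- (as.double(master) * 2654435761 + s * 40503 + as.double(unit) * 69621)
  as.integer(x %% 2147483647) + 1L
}
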