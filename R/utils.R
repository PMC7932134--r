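# Internal helpers: classed conditions and seeded-RNG discipline.

palp_error <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "palp_error"), call = call))
}

palp_warn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "palp_warning")))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generator calls are pure functions of
#' their `seed` argument and never disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    palp_error("`seed` must be a single non-missing number", "palp_domain_error")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-unit sub-seed from a base seed and a counter, staying inside
# 32-bit integer range so set.seed() accepts it.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 97561) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
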