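# internal helpers ---------------------------------------------------------

.stopf <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "glutTME_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

.assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    .stopf("invalidParameter", "'%s' must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

.assertNumber <- function(x, name, min = -Inf, max = Inf, strict = FALSE) {
  ok <- length(x) == 1L && is.finite(x) &&
    (if (strict) x > min else x >= min) && x <= max
  if (!ok)
    .stopf("invalidParameter", "'%s' must be a single finite number in the valid range", name)
  invisible(as.numeric(x))
}

# restore RNG state on exit so seeded generators do not disturb the caller
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
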