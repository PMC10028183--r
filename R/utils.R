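# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All stochastic entry points funnel through
# this so a single seed drives the whole pipeline.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Sum of f(leaf) over a nested list.
sumLeaves <- function(a, f) {
  if (is.list(a)) sum(vapply(a, sumLeaves, numeric(1), f = f)) else f(a)
}

stopNamed <- function(class, msg, call. = FALSE) {
  cnd <- structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cnd)
}
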