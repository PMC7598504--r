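# Internal helpers: structured error conditions and local RNG scope.

# All package errors carry class "topoquant_error" plus a specific subclass
# so callers (and the pipeline's exit-code mapping) can dispatch on the kind
# of failure: config vs data vs numerical.
stop_tq <- function(subclass, msg, ...) {
  stop(errorCondition(msg, ..., class = c(subclass, "topoquant_error", "error")))
}

warn_tq <- function(subclass, msg, ...) {
  warning(warningCondition(msg, ..., class = c(subclass, "topoquant_warning", "warning")))
}

# Run `expr` under a fixed seed without touching the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
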