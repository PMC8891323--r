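# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# log2(x + 1): the package-wide convention for putting linear-scale
# expression on log scale.
log2p1 <- function(x) log2(x + 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

check_surv <- function(times, events) {
  if (length(times) != length(events)) {
    stop_input("times and events must have equal length")
  }
  if (length(times) == 0L) stop_input("empty survival input")
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop_input("all survival times must be finite and > 0")
  }
  if (!all(events %in% c(0, 1))) {
    stop_input("events must be 0/1")
  }
  invisible(TRUE)
}
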