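# Internal helpers: classed conditions and local RNG scoping.

ik_abort <- function(message, class, ...) {
  data <- list(...)
  cond <- structure(
    class = c(class, "inhibkin_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
  stop(cond)
}

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ik_abort(sprintf("`%s` must be a single finite number", name),
             "inhibkin_input_error")
  }
  if (positive && x <= 0) {
    ik_abort(sprintf("`%s` must be > 0", name), "inhibkin_input_error")
  }
  if (nonneg && x < 0) {
    ik_abort(sprintf("`%s` must be >= 0", name), "inhibkin_input_error")
  }
  invisible(x)
}
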