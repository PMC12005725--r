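`%||%` <- function(a, b) if (is.null(a)) b else a

## User-facing input errors get their own condition class so the CLI can map
## them to exit code 1 (internal failures exit 2).
stop_user <- function(..., call. = FALSE) {
  msg <- paste0(...)
  stop(structure(class = c("kinegate_user_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_scalar <- function(x, name, min = -Inf, allow_inf = FALSE,
                         strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (is.finite(x) || (allow_inf && x > 0))
  if (!ok) stop_user("'", name, "' must be a single ",
                     if (allow_inf) "(possibly infinite) " else "finite ",
                     "number")
  if (strict && !(x > min)) stop_user("'", name, "' must be > ", min)
  if (!strict && x < min) stop_user("'", name, "' must be >= ", min)
  invisible(x)
}

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## stream.  Every simulator routes its randomness through this helper, so a
## call with a given seed is reproducible regardless of global state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  check_scalar(seed, "seed")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a bounded child seed for stage `i` from a global seed (keeps values
## well inside 32-bit integer range).
child_seed <- function(seed, i) {
  (as.integer(seed) * 7919L + as.integer(i) * 104729L) %% 2147483587L
}
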