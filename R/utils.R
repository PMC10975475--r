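# Shared internal helpers: classed error conditions and small numeric utilities.

abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "pktranslate_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

abort_schema <- function(msg, ...) abort(msg, "pktranslate_schema_error", ...)
abort_validation <- function(msg, ...) abort(msg, "pktranslate_validation_error", ...)
abort_io <- function(msg, ...) abort(msg, "pktranslate_io_error", ...)

warn_flag <- function(msg) warning(msg, call. = FALSE)

stopifnot_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_validation(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

stopifnot_fraction <- function(x, name, open0 = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && all(x <= 1) &&
    (if (open0) all(x > 0) else all(x >= 0))
  if (!ok) abort_validation(sprintf("`%s` must lie in %s", name,
                                    if (open0) "(0, 1]" else "[0, 1]"))
  invisible(x)
}

# Geometric-mean-preserving lognormal sd on the log scale for a given CV.
lognormal_sdlog <- function(cv) sqrt(log(1 + cv^2))

# Seed handling: run `expr` under a given integer seed without clobbering the
# caller's RNG stream; seed = NULL leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
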