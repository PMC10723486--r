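# Internal helpers: classed error conditions and seeded evaluation.

st_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "st_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_invalid    <- function(msg, ...) st_stop("st_invalid_argument", msg, ...)
stop_degenerate <- function(msg, ...) st_stop("st_degenerate_input", msg, ...)
stop_format     <- function(msg, ...) st_stop("st_format_error", msg, ...)
stop_bounds     <- function(msg, ...) st_stop("st_bounds_error", msg, ...)
stop_contract   <- function(msg, ...) st_stop("st_contract_error", msg, ...)
stop_nopath     <- function(msg, ...) st_stop("st_no_path_error", msg, ...)
stop_annotation <- function(msg, ...) st_stop("st_annotation_error", msg, ...)

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# random state. All randomness in the package flows through this helper so
# that a single integer seed determines every stochastic stage.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_invalid("seed must be a single finite number, got %s",
                 paste(seed, collapse = ","))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Timestamped, stage-scoped log line (machine-parseable: TSV fields).
st_log <- function(stage, msg, verbose = TRUE) {
  if (isTRUE(verbose))
    message(sprintf("%s\t%s\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    stage, msg))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
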