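# Internal helpers shared across modules.

#' @keywords internal
sigmoid <- function(z) 1 / (1 + exp(-z))

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL runs with the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation so the state can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# floor() with protection against representation error (e.g. 173.61 * 3
# stored as 520.8299999...): values within 1e-9 of an integer snap to it.
floor_samples <- function(x) {
  as.integer(floor(x + 1e-9))
}
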