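#' Evaluate code with a temporarily fixed RNG seed
#'
#' Sets the random seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded helpers do not disturb the global stream.
#' With `seed = NULL` the code runs against the current RNG state.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Log a pipeline message to standard error
#'
#' All stochastic steps report their configuration (alpha, repeats, folds,
#' seed, ...) through this hook so runs are auditable. Silenced with
#' `options(chemomics.quiet = TRUE)` or `suppressMessages()`.
#'
#' @param fmt `sprintf()` format string.
#' @param ... Values interpolated into `fmt`.
#' @return Invisibly, the formatted string.
#' @export
pipeline_log <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  if (!isTRUE(getOption("chemomics.quiet", FALSE))) {
    message("[chemomics] ", msg)
  }
  invisible(msg)
}

# shared stopper with consistent prefix for input-contract violations
fail_input <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
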