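# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{code} with \code{set.seed(seed)} in effect and restores the
#' caller's RNG state afterwards, so seeded package functions never disturb
#' the global random stream. A \code{NULL} seed evaluates the code under the
#' current stream.
#' @param seed integer seed or \code{NULL}.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Classed conditions: callers can distinguish "statistically undefined"
# results (zero variance, all-zero margins) from programming errors.
stop_undefined <- function(msg, call. = FALSE) {
  stop(structure(class = c("snpmdr_undefined_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_validation <- function(msg) {
  stop(structure(class = c("snpmdr_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}
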