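#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global random-number generator seeded at `seed`,
#' restoring the caller's RNG state afterwards so no global state leaks. With
#' `seed = NULL` the expression runs on the current RNG stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## largest-remainder apportionment of n into shares summing to 1
largest_remainder <- function(n, props) {
  stopifnot(abs(sum(props) - 1) < 1e-8, n >= 0)
  raw <- n * props
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[idx] <- base[idx] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)
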