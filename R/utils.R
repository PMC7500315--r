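# internal validation helpers

stop_dim <- function(...) stop(structure(
  class = c("fastbcnn_dim_error", "error", "condition"),
  list(message = paste0(...), call = sys.call(-1))
))

stop_val <- function(...) stop(structure(
  class = c("fastbcnn_validation_error", "error", "condition"),
  list(message = paste0(...), call = sys.call(-1))
))

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop_val(what, " contains non-finite values")
  invisible(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded internals do not
#' perturb the caller's random stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
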