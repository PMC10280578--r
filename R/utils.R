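#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random number generator seeded to `seed`,
#' then restores the previous RNG state, so seeded package internals do
#' not disturb the caller's random stream. With `seed = NULL` the
#' expression runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Balanced random fold labels 1..k for n rows.
make_folds <- function(n, k) {
  k <- max(2L, min(as.integer(k), n))
  sample(rep_len(seq_len(k), n))
}

# One-indicator-per-class response matrix (n x K), columns in level order.
class_indicator <- function(y) {
  y <- as.factor(y)
  K <- nlevels(y)
  Y <- matrix(0, length(y), K, dimnames = list(NULL, levels(y)))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

# argmax over rows with ties resolved to the lowest class index
row_argmax <- function(scores) max.col(scores, ties.method = "first")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hyperseed <- function(class, msg, ...) {
  stop(structure(class = c(class, "hyperseed_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
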