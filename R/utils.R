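#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded draws never disturb surrounding code.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a deterministic sub-seed
#'
#' Hashes a base seed with any number of extra keys (numbers or strings)
#' into a new positive integer seed strictly below 2^31, so independent
#' random streams can be derived reproducibly.
#'
#' @param seed Base integer seed.
#' @param ... Additional keys.
#' @return A positive integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p)) else as.numeric(p)
    h <- (h * 69069 + v + 1) %% 2147483629
  }
  as.integer(h) + 1L
}

stopif <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
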