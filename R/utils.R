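#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a global seed
#'
#' Stages of the pipeline draw from independent, reproducible RNG streams by
#' offsetting a single global seed. The result always fits in a 32-bit signed
#' integer, as required by [set.seed()].
#'
#' @param seed Global integer seed.
#' @param offset Non-negative integer stage offset.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 7919 + 104729 * as.numeric(offset)) %% 2147483647)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never clobbers user randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_damil <- function(fmt, ..., class = "damil_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop_damil(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

# Row-wise softmax that is numerically stable for large logits.
softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
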