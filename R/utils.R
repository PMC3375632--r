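`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the previous global RNG state so
#' that seeded package internals never perturb the caller's random stream.
#' A `NULL` seed leaves the current stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible child seed from a master seed
#'
#' Hashes the master seed together with a stream label (typically the
#' chromosome name) and a round number into a 31-bit seed. Each
#' chromosome/round combination gets its own stream, so results do not
#' depend on the order in which chromosomes are processed.
#'
#' @param master integer master seed.
#' @param label character stream label, e.g. a chromosome name.
#' @param round non-negative integer round index (0 for the base stream).
#' @return a positive integer seed below 2^31.
#' @export
#' @examples
#' derive_seed(1L, "chr1", 3)
derive_seed <- function(master, label = "", round = 0) {
  stopifnot(length(master) == 1, is.finite(master),
            length(label) == 1, length(round) == 1, round >= 0)
  m <- 2147483647 # 2^31 - 1; all intermediates stay below 2^53
  h <- 0
  for (code in utf8ToInt(as.character(label))) h <- (h * 131 + code) %% m
  s <- abs(as.numeric(master)) %% m
  s <- (s * 131 + h) %% m
  s <- (s * 131 + (round %% m)) %% m
  as.integer(max(1, s))
}

stop_misuse <- function(...) stop(..., call. = FALSE)
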