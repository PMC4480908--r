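#' Derive a reproducible sub-seed for a named random substream
#'
#' All randomness in the package flows from one master seed. Each data layer
#' (gene placement, counts, array noise, ...) draws from its own substream so
#' that adding a layer never perturbs the draws of another. The sub-seed is a
#' deterministic 31-bit hash of the master seed and the stream name.
#'
#' @param seed integer master seed.
#' @param stream character stream name.
#' @return an integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(stream)) {
    # 31-bit multiplicative hash; kept in double precision (< 2^53) exactly
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a named substream seed
#'
#' Sets the RNG to a substream of `seed`, evaluates `expr`, and restores the
#' caller's RNG state afterwards.
#'
#' @param seed integer master seed.
#' @param stream character stream name.
#' @param expr expression to evaluate.
#' @keywords internal
with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_msg <- function(...) stop(sprintf(...), call. = FALSE)
warn_msg <- function(...) warning(sprintf(...), call. = FALSE)
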