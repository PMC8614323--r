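#' Derive a reproducible substream seed
#'
#' Every stochastic generator in the package draws from its own named
#' substream so that adding one operation to a pipeline never perturbs the
#' draws of another. The substream seed is a deterministic hash of the master
#' seed and the stream name, folded into the 32-bit signed range R accepts.
#'
#' @param seed master integer seed.
#' @param stream character stream name, e.g. `"herd"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (code in utf8ToInt(stream)) {
    # 31-based rolling hash, kept in double precision well below 2^53
    h <- (h * 31 + code) %% 2147483629
  }
  as.integer((abs(seed) %% 2147483629 + h) %% 2147483629)
}

#' Evaluate code under a named RNG substream
#'
#' Saves and restores the caller's RNG state, so generator calls are pure
#' functions of `(seed, stream)` and never disturb the session RNG.
#'
#' @param seed master integer seed.
#' @param stream substream name.
#' @param expr expression to evaluate.
#' @keywords internal
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stream))
  expr
}
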