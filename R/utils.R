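#' Derive a reproducible child seed from a top-level seed and a stage name
#'
#' All stochastic stages of the pipeline draw their own seed from the single
#' run-level seed so that stages can be re-run independently yet
#' deterministically. The derivation is a small multiplicative hash of the
#' stage name folded into the seed modulo 2^31 - 1 (so the result is always a
#' valid R integer seed).
#'
#' @param seed integer top-level seed.
#' @param stage character scalar naming the stage (e.g. `"pileup"`).
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "pileup")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage),
            length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime; arithmetic stays exact in doubles
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  as.integer((abs(seed) %% m * 48271 + h + 1) %% (m - 1) + 1)
}

# Evaluate `expr` under a fixed RNG seed without clobbering the caller's
# RNG stream.
with_seed <- function(seed, expr) {
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

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
  invisible(NULL)
}

is_prob <- function(x) is.numeric(x) && all(x >= 0 & x <= 1)
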