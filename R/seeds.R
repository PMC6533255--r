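#' Derive a named substream seed from a master seed
#'
#' Every random stage of the pipeline consumes its own substream derived
#' deterministically from the master seed and a stage name, so changing
#' the replicate count of one stage does not perturb the draws of
#' another. The derivation is a simple polynomial string hash folded
#' into the master seed modulo 2^31 - 1.
#'
#' @param seed master seed (integer).
#' @param stream character stage name, e.g. `"imputation"`.
#' @param index optional replicate index within the stream.
#' @return an integer seed in `[1, 2^31 - 2]`, suitable for `set.seed()`.
#' @examples
#' substream_seed(1, "hypervolume")
#' substream_seed(1, "hypervolume", index = 3)
#' @export
substream_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  s <- (abs(seed) %% m)
  out <- (s * 48271 + h * 69621 + as.numeric(index) * 16807 + 1) %% m
  as.integer(if (out == 0) 1 else out)
}

#' Evaluate an expression under a local RNG state
#'
#' Seeds the generator with `seed`, evaluates `expr`, and restores the
#' caller's RNG state, so seeded stages never perturb each other.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
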