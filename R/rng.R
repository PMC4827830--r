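#' Derive an independent child seed from a root seed
#'
#' The sampling helpers draw the affinity matrix and the odor signal from
#' separate RNG streams so that, e.g., enlarging `M` does not perturb the odor
#' draw. Child seeds are derived from the root seed with a splitmix-style
#' integer hash, reduced modulo 2^31 - 1 so the result is always a valid R
#' seed. Stream order is fixed: stream 1 feeds the affinity matrix, stream 2
#' the odor signal, stream 3 any noise process.
#'
#' @param seed Integer root seed.
#' @param stream Positive integer stream index.
#' @return An integer seed.
#' @export
#' @examples
#' child_seed(42, 1)
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stream))
  # 64-bit-safe mixing in double arithmetic: all intermediates < 2^53
  z <- (abs(seed) %% 2147483647) + 1
  for (i in seq_len(stream)) {
    z <- (z * 48271) %% 2147483647 # Lehmer step
    z <- (z + 0x9E37) %% 2147483647 # offset so stream k != k applications of step alone
  }
  as.integer(z)
}

with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
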