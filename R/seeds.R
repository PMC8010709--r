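#' Derive a per-stream seed from a master seed
#'
#' Generators draw their randomness from named streams so that adding one
#' stage to a pipeline never shifts the random stream of another. The schedule
#' is a fixed integer hash of the stream name mixed with the master seed,
#' reduced modulo the Mersenne prime 2^31 - 1 so the result is a valid R
#' integer seed.
#'
#' @param master integer master seed.
#' @param stream character stream name (for example `"isotherm"`), or an
#'   integer stream index.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "motility")
#' derive_seed(1, "rupture")
#' @export
derive_seed <- function(master, stream) {
  stopifnot(length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1
  h <- if (is.character(stream)) {
    v <- 17
    for (cc in utf8ToInt(stream)) v <- (v * 31 + cc) %% m
    v
  } else {
    as.numeric(stream) %% m
  }
  # Lehmer-style mixing; all intermediates stay below 2^53
  s <- (abs(as.numeric(master)) %% m)
  s <- (s * 48271 + h) %% m
  s <- (s * 69621 + 7919) %% m
  as.integer(s %% (m - 2) + 1)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards, so generators are pure functions of their config.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
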