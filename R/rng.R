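#' Derive a child seed from a master seed and a stage label
#'
#' Every stochastic stage of the simulator draws from its own RNG stream,
#' derived deterministically from the master seed in the configuration plus a
#' stable text label naming the stage. This makes each stage reproducible
#' bit-for-bit and insensitive to how many random numbers earlier stages
#' consumed.
#'
#' The derivation is a small polynomial hash of the label folded into the
#' seed, reduced modulo 2^31 - 1 so the result is always a valid 32-bit
#' integer seed.
#'
#' @param seed integer master seed.
#' @param label character scalar naming the stream (e.g. `"dilution"`).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "dilution")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# state is restored afterwards so simulator internals never perturb user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
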