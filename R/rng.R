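#' Deterministic per-embryo substream seed
#'
#' Maps `(seed, condition, index)` to a 31-bit seed for R's Mersenne-Twister
#' generator. The condition label enters through a multiplicative string
#' hash, so reordering or adding presets never changes the stream of an
#' existing embryo, and adding embryos to a condition never perturbs earlier
#' ones.
#'
#' @param seed Integer master seed.
#' @param condition Condition label (string).
#' @param index 1-based embryo index within the condition.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
embryo_seed <- function(seed, condition, index) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (b in utf8ToInt(condition)) h <- (h * 131 + b) %% m
  # All intermediates stay below 2^53, exact in doubles.
  s <- (h * 69069) %% m
  s <- (s + (seed %% m) * 40503) %% m
  s <- (s + index * 2654435) %% m
  as.integer(s)
}

# Run expr under a temporary RNG state seeded with `seed`; restores the
# caller's RNG state afterwards.
with_embryo_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}
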