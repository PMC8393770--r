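## Evaluate code under a given seed without disturbing the caller's RNG
## stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

gauss_band <- function(wl, centre, width) exp(-0.5 * ((wl - centre) / width)^2)

## Truncated-normal draws by inverse-CDF (deterministic under the current
## RNG stream; no rejection loop).
rtnorm <- function(n, mean, sd, a, b) {
  lo <- stats::pnorm((a - mean) / sd)
  hi <- stats::pnorm((b - mean) / sd)
  mean + sd * stats::qnorm(lo + stats::runif(n) * (hi - lo))
}
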