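## Internal numeric helpers shared across modules.

## Round half away from zero (base round() is banker's rounding).
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Nearest-rank percentile: smallest sorted value v such that at least
## ceiling(p * n) of the values are <= v. p = 0 returns the minimum.
nearestRank <- function(values, p) {
  n <- length(values)
  if (n == 0L) stop("nearestRank: empty value set")
  k <- ceiling(p * n)
  if (k < 1L) k <- 1L
  sort(values, partial = k)[k]
}

## Evaluate an expression under a fixed RNG seed, restoring the caller's
## RNG state afterwards so library code never perturbs user simulations.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

## Clamped integer pixel ranges for a tile within an image of size h x w.
## Tiles use 0-based (x, y) top-left corners; matrices are 1-based [y, x].
tileRows <- function(tile, h) {
  lo <- max(tile$y + 1L, 1L); hi <- min(tile$y + tile$height, h)
  if (lo > hi) integer(0) else seq.int(lo, hi)
}

tileCols <- function(tile, w) {
  lo <- max(tile$x + 1L, 1L); hi <- min(tile$x + tile$width, w)
  if (lo > hi) integer(0) else seq.int(lo, hi)
}
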