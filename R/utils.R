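## Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## Encode unordered pairs (i < j) of 1..n as single integers, and back.
## Used to draw random prediction sets uniformly from the pair universe.
pairIndex <- function(i, j, n) {
  # index of (i, j), i < j, in the row-major upper triangle
  (i - 1) * n - i * (i + 1) / 2 + j
}

indexPair <- function(k, n) {
  # inverse of pairIndex; k in 1..n(n-1)/2
  i <- ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * k))
  j <- k - ((i - 1) * n - i * (i + 1) / 2)
  cbind(as.integer(i), as.integer(j))
}
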