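# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the global
# .Random.seed is restored afterwards so package functions never disturb the
# caller's stream. seed = NULL uses (and advances) the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

isPowerOfTwo <- function(n) {
  n <- as.integer(n)
  n >= 1L && bitwAnd(n, n - 1L) == 0L
}

# All n! permutations of 1:n as an n! x n integer matrix (n <= 8 enforced
# by callers; 8! = 40320 rows is the largest enumeration used).
allPermutations <- function(n) {
  stopifnot(n >= 1L, n <= 8L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (pos in seq_len(n)) {
    blk <- matrix(0L, nrow(sub), n)
    blk[, pos] <- n
    blk[, -pos] <- sub
    out[row + seq_len(nrow(sub)), ] <- blk
    row <- row + nrow(sub)
  }
  out
}

# Upper-triangle (i < j) values of a square matrix, column-major order.
upperTri <- function(m) m[upper.tri(m)]

# Shortest circular difference between angles in degrees, in [-180, 180).
angleDiff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d >= 180, d - 360, d)
}
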