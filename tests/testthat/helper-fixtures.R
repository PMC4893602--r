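# small fixtures shared across test files; everything is generated in
# code with fixed seeds

smallSpec <- function(width = 64, height = 64, nFrames = 50, ...) {
  frameSpec(width = width, height = height, nFrames = nFrames, ...)
}

# a synthetic calibration table: flat to 30 V, then the focal plane
# moves toward the objective while the scale shrinks slightly
testCalibration <- function() {
  v <- seq(0, 65, by = 5)
  z <- ifelse(v <= 30, 0, -(v - 30) * 8)            # um, toward objective
  sc <- 0.25 * (1 - pmax(v - 30, 0) * 0.002)
  calibrationCurve(v, z, sc)
}

# brute-force MSD oracle: the naive double loop
msdBruteForce <- function(x, y, dt, maxLag) {
  vapply(seq_len(maxLag), function(k) {
    n <- length(x)
    acc <- 0
    for (i in seq_len(n - k))
      acc <- acc + (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
    acc / (n - k)
  }, 0)
}

# exact two-sided rank-sum p by complete enumeration (no ties assumed)
exactRankSumP <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  nA <- length(a)
  Wobs <- sum(r[seq_len(nA)])
  E <- nA * (length(pooled) + 1) / 2
  combos <- utils::combn(length(pooled), nA)
  Ws <- colSums(matrix(r[combos], nrow = nA))
  mean(abs(Ws - E) >= abs(Wobs - E) - 1e-9)
}
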