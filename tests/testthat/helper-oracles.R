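# Independent brute-force oracles used to validate the package's optimized
# implementations. Everything here is written in the most literal way
# possible, on purpose, and shares no code with the package internals.

# plug-in Shannon entropy (bits) from a raw vector, via table()
oracle_entropy <- function(...) {
  p <- as.numeric(table(paste(...)))
  p <- p / sum(p)
  -sum(p * log2(p))
}

# plug-in mutual information (bits): H(X) + H(Y) - H(X,Y)
oracle_mi <- function(x, y) {
  oracle_entropy(x) + oracle_entropy(y) - oracle_entropy(x, y)
}

# plug-in conditional mutual information: H(XZ) + H(YZ) - H(XYZ) - H(Z)
oracle_cmi <- function(x, y, z) {
  oracle_entropy(x, z) + oracle_entropy(y, z) -
    oracle_entropy(x, y, z) - oracle_entropy(z)
}

# distance from each point to its k-th nearest other point, by explicit
# double loop over all pairs
oracle_kth_neighbor <- function(pts, k) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- numeric(n - 1L)
    jj <- 0L
    for (j in seq_len(n)) {
      if (j == i) next
      jj <- jj + 1L
      d[jj] <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    }
    out[i] <- sort(d)[k]
  }
  out
}

# Lin's concordance correlation with population (1/n) moments, literal form
oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (vx + vy + (mx - my)^2)
}

# moment skewness (type 1): m3 / m2^(3/2)
oracle_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3)
  m3 / m2^1.5
}

# excess kurtosis (type 1): m4 / m2^2 - 3
oracle_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2); m4 <- mean((x - m)^4)
  m4 / m2^2 - 3
}
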