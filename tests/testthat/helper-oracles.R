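# Independent brute-force oracles, deliberately written as explicit loops
# over rater pairs so they share no code path with the package internals.

# mean per-subject fraction of agreeing ordered rater pairs, complete-case
oraclePbar <- function(values) {
  n <- ncol(values)
  keep <- rowSums(!is.na(values)) == n
  Pi <- apply(values[keep, , drop = FALSE], 1, function(v) {
    agree <- 0L
    for (a in seq_len(n)) for (b in seq_len(n)) if (a != b)
      agree <- agree + (v[a] == v[b])
    agree / (n * (n - 1))
  })
  mean(Pi)
}

# coincidence matrix by explicit enumeration of ordered rating pairs
oracleCoincidence <- function(values, k) {
  o <- matrix(0, k, k)
  excluded <- 0L
  for (u in seq_len(nrow(values))) {
    v <- values[u, ]
    v <- v[!is.na(v)]
    m <- length(v)
    if (m < 2) { excluded <- excluded + 1L; next }
    for (a in seq_len(m)) for (b in seq_len(m)) if (a != b)
      o[v[a], v[b]] <- o[v[a], v[b]] + 1 / (m - 1)
  }
  list(o = o, excluded = excluded)
}

# independent transcription of the Fleiss-Nee-Landis variance formula,
# written from the marginal proportions of the complete cases
oracleFleissSE <- function(values) {
  n <- ncol(values)
  keep <- rowSums(!is.na(values)) == n
  vals <- values[keep, , drop = FALSE]
  N <- nrow(vals)
  k <- max(values, na.rm = TRUE)
  p <- sapply(seq_len(k), function(j) sum(vals == j) / (N * n))
  num <- (sum(p * (1 - p)))^2 - sum(p * (1 - p) * (1 - 2 * p))
  sqrt(num) * sqrt(2 / (N * n * (n - 1))) / sum(p * (1 - p))
}

# random coded rating matrix, optionally with missing cells
randomRatings <- function(N, n, k, pMissing = 0) {
  v <- matrix(sample.int(k, N * n, replace = TRUE), N, n)
  if (pMissing > 0) {
    idx <- which(runif(N * n) < pMissing)
    v[idx] <- NA_integer_
  }
  v
}

workedExample <- function() {
  ratingTable(rbind(c(1, 1), c(1, 1), c(2, 2), c(1, 2)))
}
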