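# Independent oracles. Each re-derives an expected value by a route that
# shares no code with the implementation it checks.

# brute-force 1-component NIPALS PLS1: explicit loops, no linear-algebra
# shortcuts shared with fitOpls
plsOracle <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  ym <- mean(y)
  yc <- y - ym
  w <- numeric(p)
  for (j in seq_len(p)) w[j] <- sum(X[, j] * yc)
  w <- w / sqrt(sum(w^2))
  t <- numeric(n)
  for (i in seq_len(n)) t[i] <- sum(X[i, ] * w)
  q <- sum(yc * t) / sum(t * t)
  list(w = w, t = t, q = q, yHat = q * t + ym)
}

# exhaustive pair-count AUC: wins + half ties over all case/control pairs
pairCountAuc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}

# independent enumeration of retained bin edges: walk down from the axis top
# in steps of `width` and drop any bin touching the open exclusion window
enumerateBins <- function(ppmMin, ppmMax, width, exclude = NULL) {
  edges <- list()
  right <- ppmMax
  while (right > ppmMin + 1e-12) {
    left <- max(right - width, ppmMin)
    keep <- TRUE
    if (!is.null(exclude) && left < exclude[2] && right > exclude[1])
      keep <- FALSE
    if (keep) edges[[length(edges) + 1L]] <- c(left, right)
    right <- right - width
  }
  do.call(rbind, edges)
}

# exact two-sided rank-sum p-value by full enumeration of group assignments
exactRankSumP <- function(x1, x0) {
  pooled <- c(x1, x0)
  n1 <- length(x1)
  ranks <- rank(pooled)
  obs <- sum(ranks[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  stats <- apply(combos, 2, function(idx) sum(ranks[idx]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# small fast simulation settings shared across tests
tinyConfig <- function(seed = NA_real_, ...) {
  simConfig(nPoints = 2048L, seed = seed, ...)
}
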