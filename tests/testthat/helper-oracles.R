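# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (enumeration, closed forms, textbook formulas) and do
# not share code with the package implementation.

# Benjamini-Hochberg by the textbook step-up definition on sorted p-values
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Mann-Whitney U as the count of pairwise wins plus half-ties
mannWhitneyBruteU <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# exact two-sided signed-rank p by enumeration over all 2^n sign vectors
signedRankEnumP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wnull <- as.vector(signs %*% r)
  pLo <- mean(Wnull <= W + 1e-9)
  pHi <- mean(Wnull >= W - 1e-9)
  min(1, 2 * min(pLo, pHi))
}

# Kaplan-Meier by the plain product formula over event times
kmProductOracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    atRisk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / atRisk)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# two-sample logrank chi-square from the textbook O-E/V risk-set sums
logrankOracle2 <- function(time, event, group) {
  lev <- unique(group)
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tt in ts) {
    atRisk <- time >= tt
    n <- sum(atRisk)
    n1 <- sum(atRisk & group == lev[1])
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == lev[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# small deterministic OmicsMatrix built by hand
makeToyMatrix <- function(values2, valuesRef, feature = "f1") {
  m <- rbind(c(values2, valuesRef))
  rownames(m) <- feature
  colnames(m) <- c(paste0("g", seq_along(values2)),
                   paste0("r", seq_along(valuesRef)))
  OmicsMatrix(m, group = rep(c("G", "REF"),
                             c(length(values2), length(valuesRef))),
              replicate = c(seq_along(values2), seq_along(valuesRef)),
              reference = "REF")
}
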