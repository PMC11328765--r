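# Independent oracles used to pin the statistical implementations.

# Brute-force maximizer of the Breslow log partial likelihood for a single
# covariate, by two-stage grid search on [-5, 5]
gridCoxBeta <- function(time, event, x) {
  pl <- function(b)
    sum(vapply(which(event == 1L), function(i)
      b * x[i] - log(sum(exp(b * x[time >= time[i]]))), numeric(1)))
  g1 <- seq(-5, 5, by = 1e-3)
  b1 <- g1[which.max(vapply(g1, pl, numeric(1)))]
  g2 <- seq(b1 - 2e-3, b1 + 2e-3, by = 1e-6)
  g2[which.max(vapply(g2, pl, numeric(1)))]
}

# Exhaustive concordant-pair AUC of a binary outcome (ties count half)
pairCountAuc <- function(y, marker) {
  m1 <- marker[y == 1L]; m0 <- marker[y == 0L]
  mean(outer(m1, m0, ">") + 0.5 * outer(m1, m0, "=="))
}

# Hand log-rank statistic: sum over event times of (O - E) in group A and
# the hypergeometric variance
handLogrank <- function(timeA, eventA, timeB, eventB) {
  tall <- c(timeA, timeB); eall <- c(eventA, eventB)
  grp <- rep(c(1L, 0L), c(length(timeA), length(timeB)))
  o <- 0; e <- 0; v <- 0
  for (t in sort(unique(tall[eall == 1L]))) {
    at <- tall >= t
    n <- sum(at); nA <- sum(at & grp == 1L)
    d <- sum(tall == t & eall == 1L)
    o <- o + sum(tall == t & eall == 1L & grp == 1L)
    e <- e + d * nA / n
    if (n > 1L)
      v <- v + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}
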