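# Independent brute-force oracles, implemented from first principles with
# choose() so they share no code path with the package functions they check.

# One-sided tail of the hypergeometric reversal test: pool the two groups,
# fix the total reversal count, enumerate the probability of drawing at least
# `k_other` reversals into the other group.
oracle_hyper_tail <- function(n_ref, k_ref, n_other, k_other) {
  total <- n_ref + n_other
  reversals <- k_ref + k_other
  if (total == 0) return(1)
  j <- seq(k_other, min(reversals, n_other))
  j <- j[reversals - j <= n_ref]
  if (length(j) == 0) return(0)
  sum(choose(reversals, j) * choose(total - reversals, n_other - j)) /
    choose(total, n_other)
}

# One-sided exact binomial tail P(X >= k | n, 1/2).
oracle_binom_tail <- function(k, n) {
  if (n == 0) return(1)
  sum(choose(n, k:n)) / 2^n
}

# Two-sided Fisher exact p for a 2x2 table: sum of the probabilities of all
# tables with the same margins whose probability does not exceed the observed
# one (with the standard 1 + 1e-7 relative tolerance).
oracle_fisher_2x2 <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  lo <- max(0, k - m2)
  hi <- min(k, m1)
  probs <- vapply(lo:hi, function(x) {
    choose(m1, x) * choose(m2, k - x) / choose(m1 + m2, k)
  }, numeric(1))
  obs <- probs[a - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Step-up BH adjustment written out longhand.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  q[ord] <- p[ord] * m / seq_len(m)
  # enforce monotonicity from the largest p downwards
  q[ord] <- rev(cummin(rev(q[ord])))
  pmin(q, 1)
}

# Product-limit estimator by hand.
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = tt, survival = NA_real_)
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$survival[i] <- s
  }
  out
}

# Two-group log-rank statistic (O - E)^2 / V by hand.
oracle_logrank <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(0, 1), c(length(time_a), length(time_b)))
  tt <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(statistic = chisq, p_value = pchisq(chisq, df = 1, lower.tail = FALSE))
}

# Canonical unordered key, for comparing pair sets in tests.
tkey <- function(a, b) paste(pmin(a, b), pmax(a, b))
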