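# Independent brute-force oracles used across the suite.  These deliberately
# avoid the code paths they check.

# Naive two-pass population variance of a percent profile.
oracle_two_pass_variance <- function(x) {
  m <- sum(x) / length(x)
  total <- 0
  for (xi in x) total <- total + (xi - m)^2
  total / length(x)
}

# Random percent profile of size n (non-degenerate).
random_profile <- function(n) {
  v <- stats::rexp(n)
  100 * v / sum(v)
}

# Two-sided Fisher p by full hypergeometric enumeration over the support,
# probability-mass convention.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Wilcoxon rank-sum p by enumeration of all rank splits
# (tie-free data only).
oracle_wilcoxon_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  u_all <- apply(splits, 2L, function(idx) sum(idx) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Per-event-time O/E/V tabulation for the two-group log-rank statistic.
oracle_logrank_chisq <- function(time, event, group) {
  group <- as.integer(factor(group)) - 1L
  o1 <- e1 <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# Cox log partial likelihood for tie-free data (no approximation needed).
oracle_partial_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Grid maximizer of the tie-free partial likelihood.
oracle_cox_beta <- function(x, time, event, lower = -5, upper = 5) {
  stats::optimize(oracle_partial_loglik, c(lower, upper), x = x,
                  time = time, event = event, maximum = TRUE,
                  tol = 1e-9)$maximum
}

# Single-hit log-likelihood in f (natural scale), for grid-search oracles.
# Zero-count terms are dropped so saturated doses do not produce 0 * log(0).
oracle_single_hit_loglik <- function(f, dose, n, k) {
  p <- 1 - exp(-dose * f)
  total <- 0
  for (i in seq_along(dose)) {
    if (k[i] > 0) total <- total + k[i] * log(p[i])
    if (n[i] - k[i] > 0) total <- total + (n[i] - k[i]) * (-dose[i] * f)
  }
  total
}
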