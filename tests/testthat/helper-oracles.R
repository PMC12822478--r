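# Independent brute-force oracles used to check the statistical primitives.
# These deliberately share no code with the package implementation.

# Exact two-sided rank-sum p by enumeration of all C(n1+n2, n1) assignments.
enum_rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign patterns.
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
}

# Brute-force BH: q_i = min_{j : p_(j) >= p_i over the step-up path} p_(j)*m/j
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, p[ord] * m / seq_len(m))
  # step-up: running minimum from the largest rank down
  q_sorted <- rev(cummin(rev(q_sorted)))
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# Hand product-limit estimator at the distinct event times.
hand_km <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  ts <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(times >= ts[i])
    d <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# Log-rank chi-square computed from first principles (O-E and hypergeometric
# variance per distinct event time); independent of the survival package.
hand_logrank_chisq <- function(times, events, group) {
  ts <- sort(unique(times[events == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == 1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v == 0) return(0)
  o_minus_e^2 / v
}

# Permutation p for the log-rank statistic: tail frequency of the chi-square
# statistic under random group-label permutations.
perm_logrank_p <- function(times, events, group, n_perm = 10000) {
  obs <- hand_logrank_chisq(times, events, group)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    g <- sample(group)
    if (hand_logrank_chisq(times, events, g) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# Unweighted KS enrichment score by direct walk over positions.
brute_ks_es <- function(n, hit_positions) {
  nh <- length(hit_positions)
  nm <- n - nh
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    run <- run + if (i %in% hit_positions) 1 / nh else -1 / nm
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Construct a background whose overall mean is exactly 0 and sd exactly 1,
# containing 4 substrate sites at exactly +1.
constructed_background <- function(n_total = 100, n_sub = 4, sub_value = 1) {
  n_rest <- n_total - n_sub
  rest <- rnorm(n_rest)
  # scale the rest so that the full vector has mean 0 and sd 1
  target_mean_rest <- -n_sub * sub_value / n_rest
  target_ss <- (n_total - 1) - n_sub * sub_value^2 -
    (n_sub * sub_value)^2 / n_total * (n_total / n_rest)
  # direct approach: affine-transform rest to hit the exact moments
  rest <- scale(rest)[, 1]  # mean 0, sd 1
  # solve sum(rest') = -n_sub*sub_value and sum(rest'^2) such that total var = 1
  s1 <- -n_sub * sub_value
  # total: sum x = 0, sum x^2 = (n_total - 1) * 1 (sd denominator n-1)
  ss_rest <- (n_total - 1) - n_sub * sub_value^2
  # rest' = a * rest + b with sum = s1 -> b = s1 / n_rest
  b <- s1 / n_rest
  a <- sqrt((ss_rest - n_rest * b^2) / sum(rest^2))
  a * rest + b
}
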