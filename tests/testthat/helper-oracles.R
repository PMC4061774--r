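# Independent oracles used to cross-check the implementation. These are
# deliberately naive re-derivations (enumeration, closed forms, brute
# force), kept free of any package internals.

# Efron-corrected Cox partial log-likelihood for a single covariate.
efron_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    s_r <- sum(exp(beta * x[R]))
    s_d <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (j in seq_len(d) - 1) ll <- ll - log(s_r - (j / d) * s_d)
  }
  ll
}

# Maximizer of the Efron partial likelihood by 1-D golden-section search.
oracle_cox_coef <- function(time, event, x, interval = c(-10, 10)) {
  stats::optimize(function(b) efron_partial_loglik(b, time, event, x),
                  interval = interval, maximum = TRUE, tol = 1e-9)$maximum
}

# Brute-force per-value median dichotomization.
oracle_dichotomize <- function(v) {
  m <- stats::median(v)
  vapply(v, function(vi) if (vi > m) 1L else -1L, integer(1))
}

# Step-up BH by the defining formula: q_i = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(pmin(1, sort(p)[i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Pearson correlation computed on midranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Hand product-limit estimator at each distinct event time.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  tibble::tibble(time = ts, surv = out)
}
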