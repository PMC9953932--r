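# Independent brute-force oracles, deliberately written with different
# machinery than the implementations they check.

# product-limit estimator by explicit risk-set loop
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# two-group log-rank chi-square by explicit observed-minus-expected sums
oracle_logrank_chisq <- function(time_a, event_a, time_b, event_b) {
  tt <- c(time_a, time_b); ev <- c(event_a, event_b)
  grp <- c(rep(1L, length(time_a)), rep(2L, length(time_b)))
  ts <- sort(unique(tt[ev == 1]))
  o_a <- e_a <- v <- 0
  for (t in ts) {
    n <- sum(tt >= t); n_a <- sum(tt >= t & grp == 1L)
    d <- sum(tt == t & ev == 1); d_a <- sum(tt == t & ev == 1 & grp == 1L)
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  (o_a - e_a)^2 / v
}

# exact permutation p-value for the log-rank statistic (small n only)
oracle_logrank_perm_p <- function(time_a, event_a, time_b, event_b) {
  tt <- c(time_a, time_b); ev <- c(event_a, event_b)
  n_a <- length(time_a); n <- length(tt)
  obs <- oracle_logrank_chisq(time_a, event_a, time_b, event_b)
  combs <- utils::combn(n, n_a)
  stats <- apply(combs, 2, function(ix) {
    oracle_logrank_chisq(tt[ix], ev[ix], tt[-ix], ev[-ix])
  })
  mean(stats >= obs - 1e-12)
}

# pooled-variance two-sample t from the textbook closed form
oracle_student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tstat, p = 2 * pt(-abs(tstat), df = nx + ny - 2))
}

# exact permutation p-value for the difference of means (small n only)
oracle_mean_perm_p <- function(x, y) {
  z <- c(x, y); nx <- length(x)
  obs <- abs(mean(x) - mean(y))
  combs <- utils::combn(length(z), nx)
  diffs <- apply(combs, 2, function(ix) abs(mean(z[ix]) - mean(z[-ix])))
  mean(diffs >= obs - 1e-12)
}

# SF = 0.1 crossing of an LQ model by bisection on the survival function
oracle_lq_iso_bisect <- function(alpha, beta, sf_level) {
  f <- function(D) exp(-alpha * D - beta * D^2) - sf_level
  uniroot(f, c(1e-9, 1e4), tol = 1e-12)$root
}

# random valid dose components for property sweeps
random_components <- function() {
  dose_components(d_b = runif(1, 0, 5), d_n = runif(1, 0, 2),
                  d_h = runif(1, 0, 2), d_gamma = runif(1, 0, 3))
}
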