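# Independent brute-force oracles. These are literal, loop-level
# reimplementations of the statistics under test and never call the
# package's (or survival's) corresponding routines.

# two-step dosage-quotient normalization, written as explicit loops
oracle_dq <- function(counts, ref_probes, ref_samples) {
  rel <- counts
  for (s in colnames(counts)) {
    med <- median(counts[ref_probes, s])
    for (p in rownames(counts)) rel[p, s] <- counts[p, s] / med
  }
  dq <- rel
  for (p in rownames(counts)) {
    ref_vals <- numeric(0)
    for (r in ref_samples) ref_vals <- c(ref_vals, rel[p, r])
    for (s in colnames(counts)) dq[p, s] <- rel[p, s] / median(ref_vals)
  }
  dq
}

# Cox partial log-likelihood for one binary covariate, Efron or Breslow
oracle_cox_loglik <- function(beta, x, time, event, ties = "efron") {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    tied <- which(time == t & event == 1)
    risk <- which(time >= t)
    d <- length(tied)
    s_risk <- sum(exp(beta * x[risk]))
    s_tied <- sum(exp(beta * x[tied]))
    ll <- ll + beta * sum(x[tied])
    if (ties == "efron") {
      for (l in seq_len(d) - 1) ll <- ll - log(s_risk - (l / d) * s_tied)
    } else {
      ll <- ll - d * log(s_risk)
    }
  }
  ll
}

# two-stage grid search maximizer of the partial likelihood
oracle_cox_grid <- function(x, time, event, ties = "efron",
                            lo = -5, hi = 5, step = 1e-4) {
  coarse <- seq(lo, hi, by = 0.01)
  ll <- vapply(coarse, oracle_cox_loglik, 0, x = x, time = time,
               event = event, ties = ties)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = step)
  ll <- vapply(fine, oracle_cox_loglik, 0, x = x, time = time,
               event = event, ties = ties)
  fine[which.max(ll)]
}

# literal product-limit loop
oracle_km <- function(time, event) {
  s <- 1
  out_t <- numeric(0); out_s <- numeric(0)
  for (t in sort(unique(time[event == 1]))) {
    d <- sum(time == t & event == 1)
    n <- sum(time >= t)
    s <- s * (1 - d / n)
    out_t <- c(out_t, t); out_s <- c(out_s, s)
  }
  list(time = out_t, surv = out_s)
}

# two-group log-rank statistic, term by term
oracle_logrank2 <- function(g, time, event) {
  g <- as.integer(factor(g)) - 1L
  U <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- sum(time == t & event == 1)
    n <- sum(time >= t)
    n1 <- sum(time >= t & g == 1L)
    d1 <- sum(time == t & event == 1 & g == 1L)
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

# two-sided Fisher p by full enumeration over the hypergeometric support
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random small survival dataset without ties
random_survdata <- function(n, p_carrier = 0.5, beta = NULL) {
  if (is.null(beta)) beta <- runif(1, -1.5, 1.5)
  x <- rbinom(n, 1, p_carrier)
  if (length(unique(x)) < 2) x[1:2] <- c(0L, 1L)
  t <- rexp(n, 0.05 * exp(beta * x))
  cens <- rexp(n, 0.03)
  time <- pmin(t, cens)
  event <- as.integer(t <= cens)
  if (sum(event) == 0) event[which.max(time)] <- 1L
  # perturb to remove ties
  time <- time + seq_len(n) * 1e-9
  list(x = x, time = time, event = event)
}
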