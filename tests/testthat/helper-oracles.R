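# Independent oracles used across the suite. These deliberately use naive
# enumeration / explicit summation, not the package's own code paths.

# Exact two-sided signed-rank p-value by enumerating all 2^n sign patterns.
enum_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p_lo <- mean(v_all <= v_obs)
  p_hi <- mean(v_all >= v_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Brute-force repeated-measures ANOVA: explicit sums of squares, explicit
# covariance entries for the Greenhouse-Geisser epsilon.
oracle_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- sum(m) / (n * k)
  cm <- numeric(k); for (j in 1:k) cm[j] <- sum(m[, j]) / n
  rm_ <- numeric(n); for (i in 1:n) rm_[i] <- sum(m[i, ]) / k
  ss_cond <- 0; for (j in 1:k) ss_cond <- ss_cond + n * (cm[j] - g)^2
  ss_subj <- 0; for (i in 1:n) ss_subj <- ss_subj + k * (rm_[i] - g)^2
  ss_tot <- 0
  for (i in 1:n) for (j in 1:k) ss_tot <- ss_tot + (m[i, j] - g)^2
  ss_err <- ss_tot - ss_cond - ss_subj
  f <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  # covariance entries by explicit summation
  s <- matrix(0, k, k)
  for (a in 1:k) for (b in 1:k)
    s[a, b] <- sum((m[, a] - cm[a]) * (m[, b] - cm[b])) / (n - 1)
  dbar <- mean(diag(s)); sbar <- mean(s)
  row_m <- rowMeans(s)
  eps <- (k^2 * (dbar - sbar)^2) /
    ((k - 1) * (sum(s^2) - 2 * k * sum(row_m^2) + k^2 * sbar^2))
  p_gg <- pf(f, eps * (k - 1), eps * (k - 1) * (n - 1), lower.tail = FALSE)
  list(f = f, eps = eps, p_gg = p_gg,
       eta2 = ss_cond / ss_tot, peta2 = ss_cond / (ss_cond + ss_err))
}

# Holm step-down adjustment by direct enumeration of the procedure.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Mean and SD of RT = 1/v under a zero-truncated normal rate, by quadrature.
# Strictly, E[1/v] diverges logarithmically from the v -> 0 tail, but the
# mass there is ~ phi(-mu/sigma) (~1e-9 for the default 2.5/0.4 rates) and a
# finite simulation never reaches it. The oracle therefore integrates over
# mu +/- 6 sigma (all realizable draws at test sample sizes), which matches
# any simulated mean to far below its Monte Carlo error.
quad_inv_rate_moments <- function(mu, sigma) {
  z <- pnorm(0, mu, sigma, lower.tail = FALSE)
  lo <- max(mu - 6 * sigma, mu / 25)
  hi <- mu + 6 * sigma
  m1 <- integrate(function(v) (1 / v) * dnorm(v, mu, sigma) / z,
                  lo, hi, rel.tol = 1e-10)$value
  m2 <- integrate(function(v) (1 / v^2) * dnorm(v, mu, sigma) / z,
                  lo, hi, rel.tol = 1e-10)$value
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

# Small synthetic trial table builder
make_trials <- function(participant, condition, rt,
                        responded = !is.na(rt)) {
  data.frame(participant = participant, condition = condition, rt = rt,
             responded = responded)
}
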