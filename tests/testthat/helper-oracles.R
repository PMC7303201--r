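# Independent oracles used across the test suite. These re-derive expected
# values by brute force / closed form and must stay independent of the
# package's own code paths.

# two-sided noncentral-t power by direct quadrature of the density
oracle_t_power <- function(n, alpha, delta, sigma) {
  df <- 2 * n - 2
  ncp <- (delta / sigma) * sqrt(n / 2)
  tc <- qt(1 - alpha / 2, df)
  # R flags precision loss when the noncentral-t density is ~1e-17 far in
  # the opposite tail; irrelevant at the tolerance used here
  suppressWarnings({
    up <- integrate(function(x) dt(x, df, ncp), tc, Inf,
                    rel.tol = 1e-10)$value
    lo <- integrate(function(x) dt(x, df, ncp), -Inf, -tc,
                    rel.tol = 1e-10)$value
  })
  up + lo
}

# closed-form normal-approximation power for the two-proportion test
oracle_prop_power <- function(n, alpha, pA, pB) {
  zc <- qnorm(1 - alpha / 2)
  d <- abs(pA - pB)
  pbar <- (pA + pB) / 2
  se0 <- sqrt(2 * pbar * (1 - pbar))
  se1 <- sqrt(pA * (1 - pA) + pB * (1 - pB))
  pnorm((sqrt(n) * d - zc * se0) / se1) +
    pnorm((-sqrt(n) * d - zc * se0) / se1)
}

# z-test (infinite-df) two-sided power for normal data
oracle_z_power <- function(n, alpha, delta, sigma) {
  zc <- qnorm(1 - alpha / 2)
  ncp <- (delta / sigma) * sqrt(n / 2)
  pnorm(ncp - zc) + pnorm(-ncp - zc)
}

# brute-force scan for the minimum sample size
oracle_min_n <- function(pw_fun, target, n_max = 60) {
  for (n in 2:n_max) if (pw_fun(n) >= target) return(n)
  NA_integer_
}

# percentile/window estimator for normal data, coded independently
oracle_normal_estimate <- function(psd, delta, k) {
  q <- function(v, p) unname(quantile(v, p / 100, type = 7))
  sigma <- q(psd, k)
  lo <- q(psd, k - 5); hi <- q(psd, k + 5)
  in_win <- psd >= lo & psd <= hi
  list(sigma = sigma, delta = q(abs(delta[in_win]), 100 - k))
}

# exhaustive search over all candidate sample-size vectors for the
# unequal-size design; ties: cost, then total n, then lexicographic
oracle_unequal <- function(opps, min_power, avg_power, n_max) {
  I <- length(opps)
  cand <- lapply(seq_len(I), function(i) 2:n_max)
  pows <- lapply(seq_len(I), function(i)
    multipower::omic_power(opps[[i]]$params, 2:n_max, opps[[i]]$alpha_star))
  grid <- as.matrix(expand.grid(cand))
  P <- sapply(seq_len(I), function(i) pows[[i]][grid[, i] - 1L])
  P <- matrix(P, ncol = I)
  minp <- if (length(min_power) == 1L) rep(min_power, I) else min_power
  ok <- rowMeans(P) >= avg_power - 1e-12
  for (i in seq_len(I)) ok <- ok & (P[, i] >= minp[i] - 1e-12)
  if (!any(ok)) return(NULL)
  g <- grid[ok, , drop = FALSE]
  costs <- vapply(opps, `[[`, numeric(1), "cost")
  cost <- as.numeric(g %*% (2 * costs))
  key <- order(cost, rowSums(g))
  g <- g[key, , drop = FALSE]; cost <- cost[key]
  top <- which(cost <= cost[1L] + 1e-9 & rowSums(g) == sum(g[1L, ]))
  cand_rows <- g[top, , drop = FALSE]
  lex <- do.call(order, as.data.frame(cand_rows))
  list(x = unname(cand_rows[lex[1L], ]), cost = cost[1L])
}

# quick manual omic for optimizer tests
mk_omic <- function(name, delta, sigma, m = 1000, p1 = 0.2, cost = 1,
                    alpha_fdr = 0.05) {
  multipower::manual_power_params(name,
                                  multipower::normal_params(delta, sigma),
                                  m = m, p1 = p1, alpha_fdr = alpha_fdr,
                                  cost = cost)
}
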