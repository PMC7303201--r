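#' Statistical power of the per-feature test for one omic
#'
#' Dispatches on the parameter class: two-sided two-sample t-test power for
#' [normal_params()] (noncentral t, equal variances), the two-group
#' negative-binomial exact test for [count_params()], and the two-sample
#' two-sided test of proportions (normal approximation) for
#' [binary_params()].
#'
#' @param params A `power_params` object.
#' @param n Replicates (observations) per group; integer vector, each >= 2.
#' @param alpha Two-sided per-test significance level, in (0, 1). For a
#'   multiple-testing design this is the FDR-adjusted level from
#'   [adjust_alpha()].
#' @param ... Passed to methods (`power_count()` accepts `method`).
#' @return Numeric vector of power values, one per element of `n`.
#' @examples
#' omic_power(normal_params(1.16, 1.05), n = 16, alpha = 0.013158)
#' @export
omic_power <- function(params, n, alpha, ...) UseMethod("omic_power")

#' @export
omic_power.normal_params <- function(params, n, alpha, ...) {
  power_normal(n, alpha, params)
}

#' @export
omic_power.count_params <- function(params, n, alpha, ...) {
  power_count(n, alpha, params, ...)
}

#' @export
omic_power.binary_params <- function(params, n, alpha, ...) {
  power_binary(n, alpha, params)
}

check_n_alpha <- function(n, alpha) {
  if (any(is.na(n)) || any(n < 2) || any(n != round(n)))
    stop("`n` must contain integers >= 2", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("`alpha` must be a single number in (0, 1)", call. = FALSE)
}

#' Two-sample t-test power for normally distributed data
#'
#' Power of the two-sided, equal-variance two-sample t test at `n` replicates
#' per group, computed from the noncentral t distribution with
#' `ncp = (delta/sigma) * sqrt(n/2)` and `df = 2n - 2`. Both rejection tails
#' are counted, so the power at `delta = 0` equals `alpha`.
#'
#' @inheritParams omic_power
#' @param params A [normal_params()] object.
#' @return Numeric vector of power values in (0, 1).
#' @export
power_normal <- function(n, alpha, params) {
  stopifnot(inherits(params, "normal_params"))
  check_n_alpha(n, alpha)
  vapply(n, function(ni) {
    if (params$delta == 0) {
      # power.t.test() rejects delta = 0; the strict two-sided power is alpha
      return(alpha)
    }
    # the strict two-sided power evaluates a noncentral-t tail that can be
    # ~1e-17; R flags the (irrelevant) precision loss there
    withCallingHandlers(
      stats::power.t.test(n = ni, delta = params$delta, sd = params$sigma,
                          sig.level = alpha, type = "two.sample",
                          alternative = "two.sided", strict = TRUE)$power,
      warning = function(w) {
        if (grepl("full precision", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }, numeric(1))
}

#' Two-sample test-of-proportions power for binary data
#'
#' Wraps `stats::power.prop.test()` (two-sided, normal approximation,
#' strict = TRUE so both rejection tails count). Symmetric in `(pA, pB)`;
#' equal proportions give power `alpha`.
#'
#' @inheritParams omic_power
#' @param params A [binary_params()] object.
#' @return Numeric vector of power values.
#' @export
power_binary <- function(n, alpha, params) {
  stopifnot(inherits(params, "binary_params"))
  check_n_alpha(n, alpha)
  vapply(n, function(ni) {
    if (params$pA == params$pB) return(alpha)
    stats::power.prop.test(n = ni, p1 = params$pA, p2 = params$pB,
                           sig.level = alpha, alternative = "two.sided",
                           strict = TRUE)$power
  }, numeric(1))
}

#' Negative-binomial exact-test power for count data
#'
#' Power of the two-group conditional exact test for NB counts (the test
#' popularized for RNA-seq differential expression), with `n` replicates per
#' group, dispersion `phi`, reference-group mean `mu`, fold change `omega`
#' and between-group sequencing-depth ratio `w`.
#'
#' Group sums are NB distributed (`S_A ~ NB(n*mu, size n/phi)`,
#' `S_B ~ NB(n*w*omega*mu, size n/phi)`). For every total `s` the null
#' conditional distribution of `S_A` given `S_A + S_B = s` is computed at the
#' conditional MLE of the common per-sample mean (`s / (n + n*w)`), the
#' two-sided rejection region is formed from all outcomes whose conditional
#' probability does not exceed that of the observed one (the "small-p"
#' region, which for equal depths coincides with `edgeR::exactTest`'s
#' doubletail p-values), and power is accumulated under the alternative.
#' `phi = 0` uses the Poisson limit, where the conditional law is binomial.
#'
#' For large expected totals (`n*mu*(1 + w*omega)` above
#' `exact_total_limit`), the exact enumeration is replaced by an asymptotic
#' normal test on the log fold change with variance
#' `1/(n*mu) + phi/n + 1/(n*w*omega*mu) + phi/n`; at such totals the two
#' agree to well under 0.01.
#'
#' @inheritParams omic_power
#' @param params A [count_params()] object.
#' @param method `"auto"` (default), `"exact"` or `"approx"`.
#' @param exact_total_limit Expected-total threshold above which `"auto"`
#'   switches to the normal approximation.
#' @return Numeric vector of power values in `[0, 1]`.
#' @references Robinson MD, Smyth GK (2008) Small-sample estimation of
#'   negative binomial dispersion, with applications to SAGE data.
#'   Biostatistics 9:321-332.
#' @export
power_count <- function(n, alpha, params, method = c("auto", "exact", "approx"),
                        exact_total_limit = 5000) {
  stopifnot(inherits(params, "count_params"))
  check_n_alpha(n, alpha)
  method <- match.arg(method)
  vapply(n, function(ni) {
    total <- ni * params$mu * (1 + params$w * params$omega)
    use_exact <- switch(method,
                        exact = TRUE,
                        approx = FALSE,
                        auto = total <= exact_total_limit)
    if (use_exact) {
      nb_exact_power(ni, alpha, params)
    } else {
      nb_approx_power(ni, alpha, params)
    }
  }, numeric(1))
}

# density of a group sum: NB with mean m and size n/phi; Poisson limit at phi=0
dsum <- function(x, m, n, phi) {
  if (phi <= 1e-12) stats::dpois(x, m) else
    stats::dnbinom(x, size = n / phi, mu = m)
}
qsum <- function(p, m, n, phi) {
  if (phi <= 1e-12) stats::qpois(p, m) else
    stats::qnbinom(p, size = n / phi, mu = m)
}

nb_exact_power <- function(n, alpha, params, eps = 1e-9) {
  phi <- params$phi; mu <- params$mu; omega <- params$omega; w <- params$w
  mA <- n * mu
  mB <- n * w * omega * mu
  slo <- qsum(eps, mA, n, phi) + qsum(eps, mB, n, phi)
  shi <- qsum(1 - eps, mA, n, phi) + qsum(1 - eps, mB, n, phi)
  pow <- 0
  for (s in slo:shi) {
    # restrict the support of a = S_A to where either the null conditional or
    # the alternative puts non-negligible mass; tails below ~1e-12 cannot
    # change the rejection region at any practical alpha
    mu0 <- s / (n + n * w)           # conditional MLE of the common mean
    a_lo <- min(qsum(1e-12, n * mu0, n, phi), qsum(1e-12, mA, n, phi))
    a_hi <- max(qsum(1 - 1e-12, n * mu0, n, phi), qsum(1 - 1e-12, mA, n, phi))
    a <- max(0, a_lo):min(s, a_hi)
    p0 <- dsum(a, n * mu0, n, phi) * dsum(s - a, n * w * mu0, n, phi)
    tot0 <- sum(p0)
    if (tot0 <= 0) next
    p0 <- p0 / tot0
    ord <- order(p0)
    cum <- cumsum(p0[ord])
    pval <- numeric(length(a))
    pval[ord] <- cum
    rej <- pval <= alpha * (1 + 1e-12)
    if (!any(rej)) next
    palt <- dsum(a[rej], mA, n, phi) * dsum(s - a[rej], mB, n, phi)
    pow <- pow + sum(palt)
  }
  min(max(pow, 0), 1)
}

nb_approx_power <- function(n, alpha, params) {
  phi <- params$phi; mu <- params$mu; omega <- params$omega; w <- params$w
  # Wald test on log(mean_B / mean_A); delta method variance of a log NB mean
  v <- 1 / (n * mu) + phi / n + 1 / (n * w * omega * mu) + phi / n
  z <- abs(log(omega)) / sqrt(v)
  zc <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(z - zc) + stats::pnorm(-z - zc)
}

#' Minimum per-group sample size reaching a target power
#'
#' Smallest integer `n >= 2` such that the per-feature power at significance
#' level `alpha` reaches `target_power`. The search exploits monotonicity of
#' power in `n` (bisection) and verifies the boundary by direct evaluation.
#'
#' @inheritParams omic_power
#' @param target_power Required power, in (0, 1).
#' @param n_max Largest sample size considered (default 200). If even
#'   `n_max` does not reach the target, the result is flagged infeasible
#'   rather than raising an error.
#' @return A list with elements `n` (integer, `NA` if infeasible), `power`
#'   (power at `n`, or at `n_max` if infeasible), and `feasible` (logical).
#' @examples
#' min_sample_size(normal_params(1.16, 1.05), alpha = 0.013158,
#'                 target_power = 0.6)
#' @export
min_sample_size <- function(params, alpha, target_power, n_max = 200) {
  stopifnot(inherits(params, "power_params"))
  if (!is.numeric(target_power) || length(target_power) != 1L ||
      is.na(target_power) || target_power <= 0 || target_power >= 1)
    stop("`target_power` must be in (0, 1)", call. = FALSE)
  if (n_max < 2) stop("`n_max` must be >= 2", call. = FALSE)
  pw <- function(n) omic_power(params, n, alpha)
  if (pw(2) >= target_power)
    return(list(n = 2L, power = pw(2), feasible = TRUE))
  p_hi <- pw(n_max)
  if (p_hi < target_power)
    return(list(n = NA_integer_, power = p_hi, feasible = FALSE))
  lo <- 2L; hi <- as.integer(n_max)      # pw(lo) < target <= pw(hi)
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2)
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  # guard against any residual non-monotonicity of the discrete exact test
  while (hi > 2L && pw(hi - 1L) >= target_power) hi <- hi - 1L
  list(n = hi, power = pw(hi), feasible = TRUE)
}
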