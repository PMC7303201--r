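#' Power parameters for normally distributed omic data
#'
#' Bundle of the two quantities that, together with the sample size and the
#' significance level, determine two-sample t-test power: the absolute
#' difference of group means to detect and the pooled standard deviation
#' (PSD) across the two groups.
#'
#' @param delta Absolute difference of group means, in data units (>= 0).
#' @param sigma Pooled standard deviation, in data units (> 0).
#' @return An object of class `c("normal_params", "power_params")`.
#' @seealso [count_params()], [binary_params()], [omic_power()]
#' @examples
#' normal_params(delta = 1.16, sigma = 1.05)
#' @export
normal_params <- function(delta, sigma) {
  stopifnot(is.numeric(delta), is.numeric(sigma), length(delta) == 1L,
            length(sigma) == 1L)
  if (is.na(delta) || delta < 0)
    stop("`delta` must be a non-negative number", call. = FALSE)
  if (is.na(sigma) || sigma <= 0)
    stop("`sigma` must be a positive number", call. = FALSE)
  structure(list(delta = delta, sigma = sigma),
            class = c("normal_params", "power_params"))
}

#' Power parameters for negative-binomial count data
#'
#' Parameters of the two-group NB exact test: the dispersion `phi` linking
#' variance and mean as `var = mu + mu^2 * phi`, the mean count `mu` in the
#' reference group A, the fold change `omega` of group B relative to A, and
#' the sequencing-depth ratio `w = D_B / D_A` between the groups.
#'
#' @param phi NB dispersion (dimensionless, >= 0; 0 is the Poisson limit).
#' @param mu Mean count in the reference group A (> 0).
#' @param omega Fold change of group B vs group A (> 0).
#' @param w Sequencing-depth ratio of group B vs group A (> 0, default 1).
#' @return An object of class `c("count_params", "power_params")`.
#' @examples
#' count_params(phi = 0.5, mu = 30, omega = 2)
#' @export
count_params <- function(phi, mu, omega, w = 1) {
  stopifnot(is.numeric(phi), is.numeric(mu), is.numeric(omega), is.numeric(w))
  if (is.na(phi) || phi < 0) stop("`phi` must be >= 0", call. = FALSE)
  if (is.na(mu) || mu <= 0) stop("`mu` must be > 0", call. = FALSE)
  if (is.na(omega) || omega <= 0) stop("`omega` must be > 0", call. = FALSE)
  if (is.na(w) || w <= 0) stop("`w` must be > 0", call. = FALSE)
  structure(list(phi = phi, mu = mu, omega = omega, w = w),
            class = c("count_params", "power_params"))
}

#' Power parameters for binary (presence/absence) data
#'
#' The two group proportions compared by the two-sample test of proportions.
#'
#' @param pA,pB Proportion of TRUE (or 1) values in groups A and B, in `[0, 1]`.
#' @return An object of class `c("binary_params", "power_params")`.
#' @examples
#' binary_params(pA = 0.2, pB = 0.7)
#' @export
binary_params <- function(pA, pB) {
  stopifnot(is.numeric(pA), is.numeric(pB))
  if (is.na(pA) || pA < 0 || pA > 1 || is.na(pB) || pB < 0 || pB > 1)
    stop("proportions must lie in [0, 1]", call. = FALSE)
  structure(list(pA = pA, pB = pB),
            class = c("binary_params", "power_params"))
}

#' @export
print.power_params <- function(x, ...) {
  type <- sub("_params$", "", class(x)[1L])
  cat(sprintf("<%s power parameters>\n", type))
  for (nm in names(x)) cat(sprintf("  %-6s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Cohen's d standardized effect size
#'
#' Cohen's d is the mean difference divided by the pooled standard deviation,
#' `d = delta / sigma`. It is scale-free and therefore comparable across omic
#' platforms with different dynamic ranges.
#'
#' @param delta Difference of group means (may be a vector).
#' @param sigma Pooled standard deviation (> 0, may be a vector).
#' @return Numeric vector of effect sizes.
#' @examples
#' cohens_d(1.16, 1.05)
#' @export
cohens_d <- function(delta, sigma) {
  if (any(is.na(sigma)) || any(sigma <= 0))
    stop("`sigma` must be positive", call. = FALSE)
  delta / sigma
}

#' Cohen's h standardized effect size for proportions
#'
#' The arcsine-transformed distance between two proportions,
#' `h = |2*asin(sqrt(pA)) - 2*asin(sqrt(pB))|`, which stabilizes the variance
#' of the proportion scale. `h` lies in `[0, pi]` and is 0 iff `pA == pB`.
#'
#' @param pA,pB Proportions in `[0, 1]` (vectorized).
#' @return Numeric vector of effect sizes.
#' @examples
#' cohens_h(0.25, 0.75)
#' @export
cohens_h <- function(pA, pB) {
  if (any(is.na(pA)) || any(pA < 0) || any(pA > 1) ||
      any(is.na(pB)) || any(pB < 0) || any(pB > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  abs(2 * asin(sqrt(pA)) - 2 * asin(sqrt(pB)))
}
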