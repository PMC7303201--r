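#' FDR-adjusted per-test significance level
#'
#' Converts a target false discovery rate into the per-test significance
#' level used by every power computation:
#' `alpha* = r1 * alpha / ((m - m1) * (1 - alpha))`,
#' where `m` is the number of features tested in the omic, `m1` the expected
#' number of truly changed features, and `r1` the expected number of true
#' detections. For normal and binary data `r1 = m1` is assumed; the same
#' default is applied to count data (a conservative simplification, since
#' `r1 <= m1`), and `r1` can be overridden.
#'
#' `m1` is taken as `m * p1` without rounding. Because `r1 = m1 = m * p1`,
#' the adjusted level depends only on the DE proportion `p1` and the FDR:
#' `alpha* = p1 * alpha / ((1 - p1) * (1 - alpha))`.
#'
#' @param m Number of features in the omic (> 0).
#' @param p1 Expected proportion of changed (DE) features, in `[0, 1)`.
#'   Ignored if `m1` is given.
#' @param alpha_fdr Target FDR, in (0, 1). Default 0.05.
#' @param m1 Expected number of changed features (default `m * p1`).
#' @param r1 Expected number of true detections (default `m1`).
#' @return The per-test significance level `alpha*` (capped at 1). A value
#'   of 0 (when `r1 = 0`) is returned with a warning, as no detections are
#'   expected.
#' @examples
#' adjust_alpha(m = 1077, p1 = 0.2, alpha_fdr = 0.05)  # 0.0131578...
#' @export
adjust_alpha <- function(m, p1 = NULL, alpha_fdr = 0.05, m1 = NULL, r1 = NULL) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m <= 0)
    stop("`m` must be a positive number", call. = FALSE)
  if (is.null(m1)) {
    if (is.null(p1)) stop("supply either `p1` or `m1`", call. = FALSE)
    if (!is.numeric(p1) || is.na(p1) || p1 < 0 || p1 > 1)
      stop("`p1` must lie in [0, 1]", call. = FALSE)
    m1 <- m * p1
  }
  if (m1 < 0 || m1 > m) stop("`m1` must lie in [0, m]", call. = FALSE)
  if (m <= m1)
    stop("`m` must exceed `m1`: the adjustment is undefined when every ",
         "feature is expected to change", call. = FALSE)
  if (is.null(r1)) r1 <- m1
  if (r1 < 0 || r1 > m1) stop("`r1` must lie in [0, m1]", call. = FALSE)
  if (!is.numeric(alpha_fdr) || is.na(alpha_fdr) || alpha_fdr <= 0 ||
      alpha_fdr >= 1)
    stop("`alpha_fdr` must be in (0, 1)", call. = FALSE)
  a <- r1 * alpha_fdr / ((m - m1) * (1 - alpha_fdr))
  if (a == 0)
    warning("r1 = 0: no true detections expected, adjusted alpha is 0",
            call. = FALSE)
  min(a, 1)
}
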