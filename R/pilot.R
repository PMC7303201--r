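#' Pilot data for one omic
#'
#' Container for one omic's pilot matrix (features x samples), the per-sample
#' group labels, the declared data type, the expected proportion of changed
#' features and the per-replicate cost. The matrix must be complete: missing
#' values must be imputed or removed upstream.
#'
#' @param name Omic label.
#' @param matrix Numeric features x samples matrix with feature row names.
#' @param groups Per-sample group labels (length `ncol(matrix)`); coerced to
#'   factor. Two-group estimation uses the first level as reference group A.
#' @param data_type One of `"normal"`, `"count"`, `"binary"`.
#' @param p1 Expected proportion of changed (DE) features.
#' @param cost Monetary cost of one replicate (used by the unequal-size
#'   optimizer).
#' @return An object of class `omic_pilot`.
#' @export
omic_pilot <- function(name, matrix, groups, data_type = c("normal", "count",
                                                           "binary"),
                       p1 = 0.2, cost = 1) {
  data_type <- match.arg(data_type)
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(matrix)))
    rownames(matrix) <- paste0("feature_", seq_len(nrow(matrix)))
  if (anyNA(matrix)) {
    idx <- which(is.na(matrix), arr.ind = TRUE)[1L, ]
    stop(sprintf(paste0("matrix of omic '%s' contains missing values ",
                        "(first at feature '%s', sample '%s'); these must be ",
                        "removed or imputed before the power analysis"),
                 name, rownames(matrix)[idx[1L]],
                 colnames(matrix)[idx[2L]] %||% idx[2L]), call. = FALSE)
  }
  groups <- factor(groups)
  if (length(groups) != ncol(matrix))
    stop("`groups` must have one label per sample (matrix column)",
         call. = FALSE)
  if (any(table(groups) < 2))
    stop("each group needs at least two replicates", call. = FALSE)
  if (data_type == "count" && any(matrix < 0))
    stop("count matrices must be non-negative", call. = FALSE)
  if (data_type == "binary" && !all(matrix %in% c(0, 1)))
    stop("binary matrices must contain only 0/1 values", call. = FALSE)
  if (!is.numeric(p1) || p1 < 0 || p1 >= 1)
    stop("`p1` must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(cost) || cost <= 0)
    stop("`cost` must be positive", call. = FALSE)
  structure(list(name = name, matrix = matrix, groups = groups,
                 data_type = data_type, p1 = p1, cost = cost),
            class = "omic_pilot")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.omic_pilot <- function(x, ...) {
  cat(sprintf("<omic_pilot '%s'>  %s data, %d features x %d samples (%s)\n",
              x$name, x$data_type, nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s: %d", levels(x$groups), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Depth-normalize a count pilot and estimate the depth ratio w
#'
#' Sequencing depth of a sample is its column sum. Each sample is divided by
#' its depth relative to the median depth across all samples (MSD), i.e. by
#' `depth_s / MSD`. The between-group depth ratio is
#' `w = D_B / D_A`, where `D_g` is the geometric mean depth of group `g`
#' divided by MSD (the MSD cancels in the ratio but is kept for the
#' per-sample scaling).
#'
#' @param pilot An [omic_pilot()] with `data_type = "count"`.
#' @return A list with `matrix` (normalized counts, same shape), `w` (depth
#'   ratio B vs A) and `depth` (raw per-sample depths).
#' @export
normalize_counts <- function(pilot) {
  stopifnot(inherits(pilot, "omic_pilot"))
  if (pilot$data_type != "count")
    stop("depth normalization applies to count data only", call. = FALSE)
  depth <- colSums(pilot$matrix)
  if (any(depth <= 0)) {
    bad <- colnames(pilot$matrix)[which(depth <= 0)[1L]] %||%
      which(depth <= 0)[1L]
    stop(sprintf("sample '%s' has zero sequencing depth", bad), call. = FALSE)
  }
  msd <- stats::median(depth)
  norm <- sweep(pilot$matrix, 2, depth / msd, "/")
  gm <- function(x) exp(mean(log(x)))
  lv <- levels(pilot$groups)
  if (length(lv) != 2)
    stop("depth ratio requires exactly two groups", call. = FALSE)
  dA <- gm(depth[pilot$groups == lv[1L]]) / msd
  dB <- gm(depth[pilot$groups == lv[2L]]) / msd
  list(matrix = norm, w = dB / dA, depth = depth)
}

#' Per-feature summary statistics of a two-group pilot
#'
#' Computes, for every feature, the group means, the mean difference
#' (group B minus reference group A), per-group variances, the pooled
#' standard deviation (PSD) and a standardized effect size `d`:
#' Cohen's d (`|delta|/PSD`) for normal data, Cohen's d of the
#' `log2(x + 1)`-transformed normalized counts for count data (so the
#' selection threshold `d0` is scale-free and comparable across omics), and
#' Cohen's h for binary data. Count pilots are depth-normalized first and
#' additionally carry the per-feature fold change `meanB / meanA` on the
#' normalized scale.
#'
#' @param pilot An [omic_pilot()] with exactly two groups.
#' @return A data frame with one row per feature (columns depend on the data
#'   type), with attributes `data_type`, `w` (count data) and `groups`.
#' @export
compute_feature_stats <- function(pilot) {
  stopifnot(inherits(pilot, "omic_pilot"))
  lv <- levels(pilot$groups)
  if (length(lv) != 2)
    stop("feature statistics require exactly two groups; use ",
         "`multigroup_design()` for more", call. = FALSE)
  iA <- pilot$groups == lv[1L]
  iB <- pilot$groups == lv[2L]
  nA <- sum(iA); nB <- sum(iB)
  if (nA < 2 || nB < 2)
    stop("each group needs at least two replicates", call. = FALSE)
  w <- NA_real_
  mat <- pilot$matrix
  if (pilot$data_type == "count") {
    nc <- normalize_counts(pilot)
    mat <- nc$matrix
    w <- nc$w
  }
  grp_stats <- function(m) {
    list(mean = rowMeans(m), var = apply(m, 1L, stats::var))
  }
  A <- grp_stats(mat[, iA, drop = FALSE])
  B <- grp_stats(mat[, iB, drop = FALSE])
  psd <- sqrt(((nA - 1) * A$var + (nB - 1) * B$var) / (nA + nB - 2))
  out <- data.frame(feature = rownames(mat),
                    meanA = A$mean, meanB = B$mean,
                    delta = B$mean - A$mean,
                    varA = A$var, varB = B$var,
                    psd = psd, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (pilot$data_type == "binary") {
    out$d <- cohens_h(out$meanA, out$meanB)
    out$psd <- NA_real_
  } else if (pilot$data_type == "count") {
    lg <- log2(mat + 1)
    lA <- grp_stats(lg[, iA, drop = FALSE])
    lB <- grp_stats(lg[, iB, drop = FALSE])
    lpsd <- sqrt(((nA - 1) * lA$var + (nB - 1) * lB$var) / (nA + nB - 2))
    dd <- abs(lB$mean - lA$mean) / lpsd
    dd[lpsd == 0] <- 0
    out$d <- dd
    out$fold_change <- ifelse(out$meanA > 0, out$meanB / out$meanA, NA_real_)
  } else {
    dd <- abs(out$delta) / out$psd
    dd[out$psd == 0] <- 0
    out$d <- dd
  }
  attr(out, "data_type") <- pilot$data_type
  attr(out, "w") <- w
  attr(out, "n_per_group") <- c(nA, nB)
  out
}

#' Select pseudo-DE features
#'
#' The estimation population for all power parameters: the features whose
#' observed standardized effect size strictly exceeds the initial Cohen's d
#' threshold `d0`.
#'
#' @param stats Output of [compute_feature_stats()].
#' @param d0 Effect-size threshold (>= 0).
#' @return Character vector of feature identifiers.
#' @export
select_pseudo_de <- function(stats, d0 = 0.8) {
  if (!is.numeric(d0) || d0 < 0) stop("`d0` must be >= 0", call. = FALSE)
  sel <- stats$feature[stats$d > d0]
  if (length(sel) == 0L)
    stop(sprintf(paste0("no pseudo-DE features at d0 = %g; lower the ",
                        "Cohen's d threshold"), d0), call. = FALSE)
  sel
}

# type-7 quantile of x at percentile k (0..100)
pctl <- function(x, k) stats::quantile(x, k / 100, type = 7, names = FALSE,
                                       na.rm = TRUE)

# indices of `values` lying in the percentile window [k-5, k+5] of `ref`;
# widens symmetrically in 5-percentile steps if the window is empty
pctl_window <- function(values, ref, k, quiet = FALSE) {
  half <- 5
  repeat {
    lo <- pctl(ref, max(0, k - half))
    hi <- pctl(ref, min(100, k + half))
    sel <- which(values >= lo & values <= hi)
    if (length(sel) > 0L) return(sel)
    if (k - half <= 0 && k + half >= 100)
      return(seq_along(values))
    half <- half + 5
    if (!quiet)
      warning(sprintf("empty percentile window; widened to +/- %d percentiles",
                      half), call. = FALSE)
  }
}

check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k <= 5 || k >= 95)
    stop("percentile `k` must lie strictly between 5 and 95", call. = FALSE)
}

#' Estimate normal-data power parameters from pseudo-DE features
#'
#' The pooled standard deviation is the percentile `P_k` of the pseudo-DE
#' PSDs (default `k = 75`, a conservative choice). To avoid tying the effect
#' size to a single feature, the mean difference is the `P_(100-k)`
#' percentile of the absolute mean differences among pseudo-DE features
#' whose PSD falls within the `[P_(k-5), P_(k+5)]` window; an empty window
#' is widened symmetrically in 5-percentile steps with a warning.
#'
#' @param stats Output of [compute_feature_stats()] for a normal-data pilot.
#' @param pseudo_de Feature identifiers from [select_pseudo_de()].
#' @param k PSD percentile, strictly between 5 and 95 (default 75).
#' @return A [normal_params()] object.
#' @export
estimate_normal_params <- function(stats, pseudo_de, k = 75) {
  check_k(k)
  s <- stats[stats$feature %in% pseudo_de, , drop = FALSE]
  if (nrow(s) == 0L) stop("empty pseudo-DE set", call. = FALSE)
  sigma <- pctl(s$psd, k)
  win <- pctl_window(s$psd, s$psd, k)
  delta <- pctl(abs(s$delta[win]), 100 - k)
  normal_params(delta = delta, sigma = sigma)
}

#' Estimate count-data power parameters from pseudo-DE features
#'
#' The per-condition variance `sigma^2` is the percentile `P_k` of the
#' per-group variances of all pseudo-DE features (both groups stacked). The
#' mean count `mu` is the `P_(100-k)` of reference-group means among
#' pseudo-DE features with a group variance inside the
#' `[P_(k-5), P_(k+5)]` variance window. The dispersion follows from the NB
#' mean-variance relation, `phi = (sigma^2 - mu) / mu^2`, floored at 0
#' (the Poisson limit). The fold change `omega` is the `P_(100-k)` of
#' direction-folded fold changes (`max(fc, 1/fc)`, so up- and down-regulation
#' are treated symmetrically) among pseudo-DE features whose PSD lies in the
#' `[P_(k-5), P_(k+5)]` PSD window; features with zero reference mean are
#' excluded. The depth ratio `w` is carried over from the normalization.
#'
#' @inheritParams estimate_normal_params
#' @param stats Output of [compute_feature_stats()] for a count-data pilot.
#' @return A [count_params()] object.
#' @export
estimate_count_params <- function(stats, pseudo_de, k = 75) {
  check_k(k)
  s <- stats[stats$feature %in% pseudo_de, , drop = FALSE]
  if (nrow(s) == 0L) stop("empty pseudo-DE set", call. = FALSE)
  v <- c(s$varA, s$varB)
  sigma2 <- pctl(v, k)
  # a feature enters the mu window if either group variance falls inside it
  winA <- pctl_window(s$varA, v, k, quiet = TRUE)
  winB <- pctl_window(s$varB, v, k, quiet = TRUE)
  win <- union(winA, winB)
  mu <- pctl(s$meanA[win], 100 - k)
  if (!is.finite(mu) || mu <= 0)
    stop("estimated reference mean count is zero; remove low-count features ",
         "or lower d0", call. = FALSE)
  phi <- max(0, (sigma2 - mu) / mu^2)
  fc <- s$fold_change
  ok <- is.finite(fc) & fc > 0
  fc <- pmax(fc[ok], 1 / fc[ok])
  fwin <- pctl_window(s$psd[ok], s$psd, k)
  omega <- pctl(fc[fwin], 100 - k)
  w <- attr(stats, "w")
  count_params(phi = phi, mu = mu, omega = omega,
               w = if (is.finite(w)) w else 1)
}

#' Estimate binary-data power parameters from pseudo-DE features
#'
#' Returns the `(pA, pB)` proportion pair of the pseudo-DE feature whose
#' Cohen's h is closest to the `P_(100-k)` percentile of the pseudo-DE
#' h distribution (ties resolved to the first feature in row order).
#'
#' @inheritParams estimate_normal_params
#' @param stats Output of [compute_feature_stats()] for a binary-data pilot.
#' @return A [binary_params()] object.
#' @export
estimate_binary_params <- function(stats, pseudo_de, k = 75) {
  check_k(k)
  s <- stats[stats$feature %in% pseudo_de, , drop = FALSE]
  if (nrow(s) == 0L) stop("empty pseudo-DE set", call. = FALSE)
  target <- pctl(s$d, 100 - k)
  pick <- which.min(abs(s$d - target))
  binary_params(pA = s$meanA[pick], pB = s$meanB[pick])
}

#' Remove low-count features from a count pilot
#'
#' Convenience filter dropping features whose overall mean count falls below
#' `min_mean` (default 1). Recommended before power estimation on sparse
#' sequencing data; not applied automatically.
#'
#' @param pilot A count-data [omic_pilot()].
#' @param min_mean Minimum mean raw count to keep a feature.
#' @return The filtered `omic_pilot`.
#' @export
filter_low_counts <- function(pilot, min_mean = 1) {
  stopifnot(inherits(pilot, "omic_pilot"), pilot$data_type == "count")
  keep <- rowMeans(pilot$matrix) >= min_mean
  pilot$matrix <- pilot$matrix[keep, , drop = FALSE]
  pilot
}

#' Estimate all power parameters of one omic from pilot data
#'
#' Runs the full pilot-estimation pipeline: (count data only)
#' depth-normalization and depth-ratio estimation, per-feature statistics,
#' pseudo-DE selection at the Cohen's d threshold `d0`, percentile-based
#' parameter estimation, and the FDR adjustment of the significance level.
#'
#' @param pilot An [omic_pilot()] with exactly two groups.
#' @param d0 Initial Cohen's d threshold defining pseudo-DE features.
#' @param k Percentile for dispersion estimation (default 75).
#' @param alpha_fdr Target FDR used for the adjusted significance level.
#' @return An object of class `omic_power_params`: a list with the omic
#'   `name`, `data_type`, estimated `params` (a `power_params` object),
#'   `alpha_star`, the testing budget (`m`, `p1`), the pseudo-DE set size
#'   `n_pseudo`, settings (`d0`, `k`, `alpha_fdr`), the per-replicate `cost`
#'   and the full per-feature `stats` table (kept for the power-study
#'   diagnostics).
#' @examples
#' pilot <- gen_normal_omic(m = 500, n = 10, p1 = 0.3, delta = 2, sigma = 1,
#'                          seed = 1)
#' estimate_power_params(pilot, d0 = 0.8)
#' @export
estimate_power_params <- function(pilot, d0 = 0.8, k = 75, alpha_fdr = 0.05) {
  stopifnot(inherits(pilot, "omic_pilot"))
  stats <- compute_feature_stats(pilot)
  pseudo <- select_pseudo_de(stats, d0)
  params <- switch(pilot$data_type,
                   normal = estimate_normal_params(stats, pseudo, k),
                   count = estimate_count_params(stats, pseudo, k),
                   binary = estimate_binary_params(stats, pseudo, k))
  structure(list(name = pilot$name,
                 data_type = pilot$data_type,
                 params = params,
                 alpha_star = adjust_alpha(m = nrow(pilot$matrix),
                                           p1 = pilot$p1,
                                           alpha_fdr = alpha_fdr),
                 m = nrow(pilot$matrix), p1 = pilot$p1,
                 n_pseudo = length(pseudo),
                 d0 = d0, k = k, alpha_fdr = alpha_fdr,
                 cost = pilot$cost,
                 stats = stats),
            class = "omic_power_params")
}

#' Assemble power parameters without pilot data
#'
#' Builds an `omic_power_params` object directly from user-specified power
#' parameters, for designs without pilot data (see
#' [defaults_without_pilot()] for recommended values).
#'
#' @param name Omic label.
#' @param params A `power_params` object.
#' @param m Number of features tested.
#' @param p1 Expected DE proportion.
#' @param alpha_fdr Target FDR.
#' @param cost Per-replicate cost.
#' @return An `omic_power_params` object (without per-feature statistics).
#' @export
manual_power_params <- function(name, params, m, p1, alpha_fdr = 0.05,
                                cost = 1) {
  stopifnot(inherits(params, "power_params"))
  data_type <- switch(class(params)[1L],
                      normal_params = "normal",
                      count_params = "count",
                      binary_params = "binary")
  structure(list(name = name, data_type = data_type, params = params,
                 alpha_star = adjust_alpha(m = m, p1 = p1,
                                           alpha_fdr = alpha_fdr),
                 m = m, p1 = p1, n_pseudo = NA_integer_,
                 d0 = NA_real_, k = NA_real_, alpha_fdr = alpha_fdr,
                 cost = cost, stats = NULL),
            class = "omic_power_params")
}

#' @export
print.omic_power_params <- function(x, ...) {
  cat(sprintf("<omic_power_params '%s'> %s data, m = %d, p1 = %g, alpha* = %.6g\n",
              x$name, x$data_type, x$m, x$p1, x$alpha_star))
  print(x$params)
  invisible(x)
}
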