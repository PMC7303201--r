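#' Power curve over a range of sample sizes
#'
#' Tabulates per-feature power against the per-group sample size for one or
#' several omics, at each omic's adjusted significance level. Pure plumbing
#' over [omic_power()]: the curve values equal pointwise power calls.
#'
#' @param opps An `omic_power_params` object or a list of them.
#' @param n_range Integer vector of sample sizes (default `2:35`).
#' @return A data frame with columns `omic`, `n`, `power`.
#' @export
power_vs_n <- function(opps, n_range = 2:35) {
  if (inherits(opps, "omic_power_params")) opps <- list(opps)
  do.call(rbind, lapply(opps, function(o)
    data.frame(omic = o$name, n = n_range,
               power = omic_power(o$params, n_range, o$alpha_star),
               stringsAsFactors = FALSE)))
}

#' Power curves at different dispersion percentiles
#'
#' Recomputes the power curve of an omic for several percentiles of the
#' pseudo-DE dispersion distribution (PSD for normal data, per-condition
#' variance hence NB dispersion for count data), keeping the effect-size
#' estimate of the main design fixed. Higher dispersion percentiles give
#' pointwise lower power, showing how sensitive the design is to the
#' (conservative) default `k = 75`.
#'
#' @param opp An `omic_power_params` estimated from pilot data (it must
#'   carry per-feature statistics).
#' @param percentiles Dispersion percentiles, each strictly between 5
#'   and 95.
#' @param n_range Integer vector of sample sizes.
#' @return A data frame with columns `omic`, `percentile`, `n`, `power`.
#' @export
power_vs_dispersion <- function(opp, percentiles = c(60, 75, 90),
                                n_range = 2:35) {
  stopifnot(inherits(opp, "omic_power_params"))
  if (is.null(opp$stats))
    stop("dispersion curves require pilot data (per-feature statistics)",
         call. = FALSE)
  if (opp$data_type == "binary")
    stop("binary data has no dispersion parameter", call. = FALSE)
  for (k in percentiles) check_k(k)
  stats <- opp$stats
  pseudo <- select_pseudo_de(stats, opp$d0)
  s <- stats[stats$feature %in% pseudo, , drop = FALSE]
  rows <- lapply(percentiles, function(k) {
    p <- opp$params
    if (opp$data_type == "normal") {
      p$sigma <- pctl(s$psd, k)
    } else {
      sigma2 <- pctl(c(s$varA, s$varB), k)
      p$phi <- max(0, (sigma2 - p$mu) / p$mu^2)
    }
    data.frame(omic = opp$name, percentile = k, n = n_range,
               power = omic_power(p, n_range, opp$alpha_star),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Optimal sample size as a function of the Cohen's d threshold
#'
#' Explores the trade-off between the effect size one is willing to target
#' and the sample size required: for a grid of Cohen's d thresholds from the
#' design's `d0` up to `d_max`, all omic parameters are re-estimated with
#' that threshold (the pseudo-DE set shrinks as d grows) and the equal-size
#' design is re-solved. `d_max` is the smallest of the per-omic 90th
#' percentiles of the feature-level Cohen's d values, which guarantees every
#' omic keeps at least 10% of its features as pseudo-DE for estimation.
#'
#' @param opps List of `omic_power_params` estimated from pilot data.
#' @param constraints A [design_constraints()] object.
#' @param n_target Optional available sample size; if given, the smallest
#'   grid d whose optimal size is at most `n_target` is reported.
#' @param grid_size Number of d values (default 40).
#' @return A data frame with columns `d` and `optSampleSize`, with
#'   attributes `d_max` and (if requested) `d_for_n_target`.
#' @export
post_d_grid <- function(opps, constraints = design_constraints(),
                        n_target = NULL, grid_size = 40) {
  if (inherits(opps, "omic_power_params")) opps <- list(opps)
  if (any(vapply(opps, function(o) is.null(o$stats), logical(1))))
    stop("the d-grid analysis requires pilot data for every omic",
         call. = FALSE)
  d0 <- min(vapply(opps, `[[`, numeric(1), "d0"))
  d_max <- min(vapply(opps, function(o) pctl(o$stats$d, 90), numeric(1)))
  if (d0 >= d_max)
    stop(sprintf(paste0("d0 = %.3g is not below d_max = %.3g (the smallest ",
                        "per-omic 90th percentile of feature effect sizes); ",
                        "choose a smaller d0"), d0, d_max), call. = FALSE)
  dgrid <- seq(d0, d_max, length.out = grid_size)
  opt <- vapply(dgrid, function(d) {
    re <- lapply(opps, function(o) {
      pseudo <- select_pseudo_de(o$stats, d)
      params <- switch(o$data_type,
                       normal = estimate_normal_params(o$stats, pseudo, o$k),
                       count = estimate_count_params(o$stats, pseudo, o$k),
                       binary = estimate_binary_params(o$stats, pseudo, o$k))
      o$params <- params
      o
    })
    res <- solve_equal(re, constraints)
    if (res$feasible) res$summary$optSampleSize[1L] else NA_integer_
  }, integer(1))
  out <- data.frame(d = dgrid, optSampleSize = opt)
  attr(out, "d_max") <- d_max
  if (!is.null(n_target)) {
    ok <- which(!is.na(out$optSampleSize) & out$optSampleSize <= n_target)
    attr(out, "d_for_n_target") <-
      if (length(ok)) out$d[ok[1L]] else NA_real_
    attr(out, "n_target") <- n_target
  }
  out
}

#' Multi-group power study via pairwise comparisons
#'
#' For pilot data with three or more groups, runs the two-group design
#' pipeline on every requested pair of groups (all pairs by default) and
#' reports the global optimal sample size as the maximum over comparisons,
#' so that every pairwise contrast reaches its required power.
#'
#' @param pilots List of [omic_pilot()] objects sharing group labels.
#' @param comparisons Optional list of length-2 character vectors naming the
#'   group pairs to compare; default all pairs.
#' @param d0,k,alpha_fdr Estimation settings, as in
#'   [estimate_power_params()].
#' @param constraints A [design_constraints()] object.
#' @return An object of class `multigroup_design`: list with
#'   `per_comparison` (named list of `design_result`), `global_opt` and a
#'   `summary` data frame.
#' @export
multigroup_design <- function(pilots, comparisons = NULL, d0 = 0.8, k = 75,
                              alpha_fdr = 0.05,
                              constraints = design_constraints()) {
  stopifnot(all(vapply(pilots, inherits, logical(1), "omic_pilot")))
  all_groups <- sort(unique(unlist(lapply(pilots, function(p)
    levels(p$groups)))))
  if (is.null(comparisons)) {
    comparisons <- utils::combn(all_groups, 2, simplify = FALSE)
  }
  for (cmp in comparisons) {
    if (length(cmp) != 2L || !all(cmp %in% all_groups))
      stop(sprintf("unknown group label in comparison (%s); known groups: %s",
                   paste(cmp, collapse = " vs "),
                   paste(all_groups, collapse = ", ")), call. = FALSE)
  }
  per <- lapply(comparisons, function(cmp) {
    sub <- lapply(pilots, function(p) {
      keep <- p$groups %in% cmp
      omic_pilot(p$name, p$matrix[, keep, drop = FALSE],
                 factor(p$groups[keep], levels = cmp),
                 data_type = p$data_type, p1 = p$p1, cost = p$cost)
    })
    opps <- lapply(sub, estimate_power_params, d0 = d0, k = k,
                   alpha_fdr = alpha_fdr)
    solve_equal(opps, constraints)
  })
  names(per) <- vapply(comparisons, paste, character(1), collapse = "_vs_")
  opt <- vapply(per, function(r)
    if (r$feasible) r$summary$optSampleSize[1L] else NA_integer_, integer(1))
  summ <- data.frame(comparison = names(per), optSampleSize = opt,
                     avg_power = vapply(per, `[[`, numeric(1), "avg_power"),
                     feasible = vapply(per, `[[`, logical(1), "feasible"),
                     stringsAsFactors = FALSE)
  structure(list(per_comparison = per,
                 global_opt = if (all(summ$feasible)) max(opt) else
                   NA_integer_,
                 summary = summ),
            class = "multigroup_design")
}

#' @export
print.multigroup_design <- function(x, ...) {
  cat("<multigroup_design>\n")
  print(x$summary, row.names = FALSE, digits = 4)
  cat(sprintf("global optimal sample size: %s\n", x$global_opt))
  invisible(x)
}

#' Recommended power parameters in the absence of pilot data
#'
#' Field-informed defaults for designs without prior data: a per-feature
#' standard deviation of 1 for normal data (with the mean difference set to
#' `d0 * sigma` so the targeted Cohen's d is `d0`); a minimum fold change of
#' 2 and a mean count of 30 for count data, with a conservative dispersion
#' of 0.5; and for binary data a reference proportion of 0.5 with the
#' second proportion placed a Cohen's h of `d0` away. All values require
#' review against the platform at hand.
#'
#' @param d0 Targeted standardized effect size (default 0.8).
#' @return Named list with elements `normal`, `count`, `binary`, each a
#'   `power_params` object.
#' @export
defaults_without_pilot <- function(d0 = 0.8) {
  pB <- sin(min(asin(sqrt(0.5)) + d0 / 2, pi / 2))^2
  list(normal = normal_params(delta = d0 * 1, sigma = 1),
       count = count_params(phi = 0.5, mu = 30, omega = 2, w = 1),
       binary = binary_params(pA = 0.5, pB = pB))
}

#' Plot power curves
#'
#' @param curves Data frame from [power_vs_n()] (or
#'   [power_vs_dispersion()], in which case curves are faceted by
#'   percentile).
#' @param optimal_n Optional optimal sample size to mark on each curve.
#' @param min_power Optional horizontal reference line.
#' @return A ggplot object.
#' @export
plot_power_curves <- function(curves, optimal_n = NULL, min_power = NULL) {
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$n, y = .data$power,
                                            colour = .data$omic)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "replicates per group", y = "statistical power") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
  if ("percentile" %in% names(curves))
    p <- p + ggplot2::facet_wrap(~percentile)
  if (!is.null(min_power))
    p <- p + ggplot2::geom_hline(yintercept = min_power, linetype = 2)
  if (!is.null(optimal_n))
    p <- p + ggplot2::geom_point(data = curves[curves$n == optimal_n, ,
                                               drop = FALSE],
                                 shape = 15, size = 2)
  p
}
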