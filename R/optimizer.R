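#' Constraints of the sample-size optimization
#'
#' @param min_power Minimum power required for every omic (scalar, or one
#'   value per omic).
#' @param avg_power Minimum average power across omics.
#' @param equal_size Require the same sample size for all omics?
#' @param n_max Largest admissible per-group sample size (scalar or per
#'   omic).
#' @return An object of class `design_constraints`.
#' @examples
#' design_constraints(min_power = 0.6, avg_power = 0.8)
#' @export
design_constraints <- function(min_power = 0.6, avg_power = 0.8,
                               equal_size = TRUE, n_max = 200) {
  if (any(min_power <= 0) || any(min_power >= 1) ||
      avg_power <= 0 || avg_power >= 1)
    stop("powers must lie in (0, 1)", call. = FALSE)
  if (any(n_max < 2)) stop("`n_max` must be >= 2", call. = FALSE)
  structure(list(min_power = min_power, avg_power = avg_power,
                 equal_size = equal_size, n_max = n_max),
            class = "design_constraints")
}

expand_per_omic <- function(x, I, what) {
  if (length(x) == 1L) rep(x, I)
  else if (length(x) == I) x
  else stop(sprintf("`%s` must be scalar or one value per omic", what),
            call. = FALSE)
}

# power of omic i (an omic_power_params) at n, memoized per call via closure
omic_power_fun <- function(opp) {
  force(opp)
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]]))
      cache[[key]] <- omic_power(opp$params, n, opp$alpha_star)
    cache[[key]]
  }
}

new_design_result <- function(summary, total_cost, avg_power, feasible,
                              equal_size, constraints, message = NULL) {
  structure(list(summary = summary, total_cost = total_cost,
                 avg_power = avg_power, feasible = feasible,
                 equal_size = equal_size, constraints = constraints,
                 message = message),
            class = "design_result")
}

design_summary_row <- function(opp, min_n, opt_n, power) {
  p <- opp$params
  eff <- switch(opp$data_type,
                normal = c(p$delta, p$sigma),
                count = c(p$omega, p$phi),
                binary = c(cohens_h(p$pA, p$pB), NA_real_))
  data.frame(omic = opp$name, data_type = opp$data_type,
             numFeat = opp$m, DEperc = opp$p1,
             delta = eff[1L], dispersion = eff[2L],
             alpha_star = opp$alpha_star,
             minSampleSize = min_n, optSampleSize = opt_n,
             power = power, cost = opp$cost,
             stringsAsFactors = FALSE)
}

#' Optimal equal sample size across omics
#'
#' Solves the cost-minimization design under the constraint that every omic
#' uses the same number of replicates per group. The solution is direct:
#' take the maximum of the per-omic minimum sample sizes (each the smallest
#' `n` meeting that omic's minimum power at its adjusted significance
#' level); if the average power across omics at that `n` already meets the
#' average-power constraint it is optimal, otherwise `n` is increased until
#' it does. Per-replicate costs do not influence the equal-size solution.
#'
#' @param opps List of `omic_power_params` (from [estimate_power_params()]
#'   or [manual_power_params()]).
#' @param constraints A [design_constraints()] object.
#' @return A `design_result`: per-omic summary table (Table-style layout
#'   with `minSampleSize`, `optSampleSize` and achieved `power`), total cost
#'   (`2 * sum(cost) * n`), average power, and a feasibility flag. When
#'   infeasible, `message` names the binding omic.
#' @examples
#' opps <- list(
#'   manual_power_params("prot", normal_params(1.16, 1.05), m = 1077, p1 = 0.2),
#'   manual_power_params("metab", normal_params(1.20, 0.52), m = 60, p1 = 0.6))
#' solve_equal(opps, design_constraints(0.6, 0.8))
#' @export
solve_equal <- function(opps, constraints = design_constraints()) {
  stopifnot(all(vapply(opps, inherits, logical(1), "omic_power_params")))
  I <- length(opps)
  Pmin <- expand_per_omic(constraints$min_power, I, "min_power")
  nmax <- expand_per_omic(constraints$n_max, I, "n_max")
  pfun <- lapply(opps, omic_power_fun)
  mins <- vector("list", I)
  for (i in seq_len(I)) {
    mins[[i]] <- min_sample_size(opps[[i]]$params, opps[[i]]$alpha_star,
                                 Pmin[i], n_max = nmax[i])
    if (!mins[[i]]$feasible) {
      summ <- do.call(rbind, lapply(seq_len(I), function(j)
        design_summary_row(opps[[j]],
                           if (j == i) NA_integer_ else mins[[j]]$n %||% NA,
                           NA_integer_, NA_real_)))
      return(new_design_result(summ, NA_real_, NA_real_, FALSE, TRUE,
                               constraints,
                               sprintf(paste0("omic '%s' cannot reach power ",
                                              "%.3g within n_max = %d"),
                                       opps[[i]]$name, Pmin[i], nmax[i])))
    }
  }
  min_n <- vapply(mins, `[[`, integer(1), "n")
  cap <- min(nmax)
  x <- max(min_n)
  repeat {
    pw <- vapply(seq_len(I), function(i) pfun[[i]](x), numeric(1))
    if (mean(pw) >= constraints$avg_power) break
    if (x >= cap) {
      summ <- do.call(rbind, lapply(seq_len(I), function(i)
        design_summary_row(opps[[i]], min_n[i], NA_integer_, pw[i])))
      return(new_design_result(summ, NA_real_, mean(pw), FALSE, TRUE,
                               constraints,
                               sprintf(paste0("average power %.3f at the ",
                                              "n_max cap (%d) is below %.3g"),
                                       mean(pw), cap, constraints$avg_power)))
    }
    x <- x + 1L
  }
  summ <- do.call(rbind, lapply(seq_len(I), function(i)
    design_summary_row(opps[[i]], min_n[i], x, pw[i])))
  costs <- vapply(opps, `[[`, numeric(1), "cost")
  new_design_result(summ, sum(2 * costs * x), mean(pw), TRUE, TRUE,
                    constraints)
}

#' Cost-optimal unequal sample sizes across omics
#'
#' Solves the 0-1 integer program that assigns each omic its own sample
#' size: minimize the total cost `sum_i 2 c_i x_i` subject to each omic
#' meeting its minimum power and the unweighted mean power meeting the
#' average-power constraint. The solver is an exact branch-and-bound over
#' the per-omic candidate sizes (from the per-omic minimum to `n_max`),
#' with candidates that add cost without adding power removed, and is
#' certified against exhaustive enumeration in the test suite. Ties among
#' equal-cost optima are broken toward the smaller total sample size, then
#' lexicographically.
#'
#' @inheritParams solve_equal
#' @return A `design_result` with per-omic `optSampleSize` and the minimum
#'   total cost; infeasible instances are flagged rather than raising.
#' @export
solve_unequal <- function(opps, constraints = design_constraints(
                            equal_size = FALSE)) {
  stopifnot(all(vapply(opps, inherits, logical(1), "omic_power_params")))
  I <- length(opps)
  Pmin <- expand_per_omic(constraints$min_power, I, "min_power")
  nmax <- expand_per_omic(constraints$n_max, I, "n_max")
  costs <- vapply(opps, `[[`, numeric(1), "cost")

  cand_n <- vector("list", I)
  cand_p <- vector("list", I)
  min_n <- integer(I)
  for (i in seq_len(I)) {
    ms <- min_sample_size(opps[[i]]$params, opps[[i]]$alpha_star, Pmin[i],
                          n_max = nmax[i])
    if (!ms$feasible) {
      summ <- do.call(rbind, lapply(seq_len(I), function(j)
        design_summary_row(opps[[j]], NA_integer_, NA_integer_, NA_real_)))
      return(new_design_result(summ, NA_real_, NA_real_, FALSE, FALSE,
                               constraints,
                               sprintf(paste0("omic '%s' cannot reach power ",
                                              "%.3g within n_max = %d"),
                                       opps[[i]]$name, Pmin[i], nmax[i])))
    }
    min_n[i] <- ms$n
    ns <- ms$n:nmax[i]
    ps <- omic_power(opps[[i]]$params, ns, opps[[i]]$alpha_star)
    ps <- cummax(ps)  # exact-test discreteness guard; increments are >= 0
    # drop candidates whose power does not exceed the previous one: same or
    # lower power at strictly higher cost can never be optimal
    keep <- c(TRUE, diff(ps) > 0)
    cand_n[[i]] <- ns[keep]
    cand_p[[i]] <- ps[keep]
  }

  S_needed <- I * constraints$avg_power
  base_p <- vapply(cand_p, `[`, numeric(1), 1L)
  if (sum(vapply(cand_p, max, numeric(1))) < S_needed - 1e-12) {
    summ <- do.call(rbind, lapply(seq_len(I), function(i)
      design_summary_row(opps[[i]], min_n[i], NA_integer_, NA_real_)))
    return(new_design_result(summ, NA_real_, NA_real_, FALSE, FALSE,
                             constraints,
                             "average-power constraint unreachable even at n_max"))
  }

  better <- function(cost_a, x_a, cost_b, x_b) {
    # is solution a strictly preferred to b? (cost, then sum(n), then lexico)
    if (cost_a < cost_b - 1e-9) return(TRUE)
    if (cost_a > cost_b + 1e-9) return(FALSE)
    if (sum(x_a) != sum(x_b)) return(sum(x_a) < sum(x_b))
    d <- which(x_a != x_b)
    length(d) > 0L && x_a[d[1L]] < x_b[d[1L]]
  }

  if (sum(base_p) >= S_needed - 1e-12) {
    # per-omic minima already satisfy the average constraint: optimal, since
    # any feasible solution dominates them componentwise in cost
    x <- min_n
  } else {
    ord <- order(costs, decreasing = TRUE)   # branch on expensive omics first
    cn <- cand_n[ord]; cp <- cand_p[ord]; cc <- costs[ord]
    suffix_min_cost <- rev(cumsum(rev(2 * cc * vapply(cn, `[`, numeric(1), 1L))))
    suffix_max_pow <- rev(cumsum(rev(vapply(cp, max, numeric(1)))))
    suffix_min_cost <- c(suffix_min_cost, 0)
    suffix_max_pow <- c(suffix_max_pow, 0)

    # greedy incumbent: raise the size with the best power gain per cost
    gx <- rep(1L, I)  # candidate indices
    repeat {
      S <- sum(vapply(seq_len(I), function(i) cp[[i]][gx[i]], numeric(1)))
      if (S >= S_needed - 1e-12) break
      gain <- vapply(seq_len(I), function(i) {
        if (gx[i] >= length(cp[[i]])) return(-Inf)
        dp <- cp[[i]][gx[i] + 1L] - cp[[i]][gx[i]]
        dcost <- 2 * cc[i] * (cn[[i]][gx[i] + 1L] - cn[[i]][gx[i]])
        dp / dcost
      }, numeric(1))
      j <- which.max(gain)
      gx[j] <- gx[j] + 1L
    }
    best_x <- vapply(seq_len(I), function(i) cn[[i]][gx[i]], integer(1))
    best_cost <- sum(2 * cc * best_x)

    x_cur <- integer(I)
    recurse <- function(i, cost, pow) {
      if (i > I) {
        if (pow >= S_needed - 1e-12 &&
            better(cost, x_cur, best_cost, best_x)) {
          best_cost <<- cost
          best_x <<- x_cur
        }
        return(invisible())
      }
      for (j in seq_along(cn[[i]])) {
        ncost <- cost + 2 * cc[i] * cn[[i]][j]
        if (ncost + suffix_min_cost[i + 1L] > best_cost + 1e-9) break
        npow <- pow + cp[[i]][j]
        if (npow + suffix_max_pow[i + 1L] < S_needed - 1e-12) next
        x_cur[i] <<- cn[[i]][j]
        recurse(i + 1L, ncost, npow)
      }
      invisible()
    }
    recurse(1L, 0, 0)
    x <- integer(I)
    x[ord] <- best_x
  }

  pw <- vapply(seq_len(I), function(i)
    omic_power(opps[[i]]$params, x[i], opps[[i]]$alpha_star), numeric(1))
  summ <- do.call(rbind, lapply(seq_len(I), function(i)
    design_summary_row(opps[[i]], min_n[i], x[i], pw[i])))
  new_design_result(summ, sum(2 * costs * x), mean(pw), TRUE, FALSE,
                    constraints)
}

#' Summary table of a design result
#'
#' One row per omic in the layout of the method's published summary:
#' `numFeat`, `DEperc`, `delta`, `dispersion`, `minSampleSize`,
#' `optSampleSize`, `power` (plus the data type, adjusted significance and
#' per-replicate cost).
#'
#' @param object A `design_result`.
#' @param ... Unused.
#' @return A data frame.
#' @export
summary.design_result <- function(object, ...) object$summary

#' @export
as.data.frame.design_result <- function(x, ...) x$summary

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("<design_result> %s sample sizes, %s\n",
              if (x$equal_size) "equal" else "unequal",
              if (x$feasible) "feasible" else "INFEASIBLE"))
  if (!is.null(x$message)) cat("  ", x$message, "\n", sep = "")
  print(x$summary, digits = 4, row.names = FALSE)
  if (x$feasible)
    cat(sprintf("total cost: %g   average power: %.3f\n",
                x$total_cost, x$avg_power))
  invisible(x)
}

#' Write a design result to TSV and JSON
#'
#' @param result A `design_result`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_design <- function(result, dir, prefix = "design") {
  stopifnot(inherits(result, "design_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(prefix, "_summary.tsv"))
  utils::write.table(result$summary, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(summary = result$summary,
                            total_cost = result$total_cost,
                            avg_power = result$avg_power,
                            feasible = result$feasible,
                            equal_size = result$equal_size),
                       js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv = tsv, json = js))
}
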