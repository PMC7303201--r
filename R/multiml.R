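#' Multi-omic classification dataset
#'
#' Bundles a list of omic matrices (observations x variables, with shared
#' observation identifiers in the row names) and the per-observation class
#' labels.
#'
#' @param X Named list of numeric matrices with observation row names.
#' @param Y Factor (or vector) of class labels, named by observation
#'   identifier (or aligned with the first matrix).
#' @return An object of class `multiomic_ml_data`.
#' @export
multiomic_ml_data <- function(X, Y) {
  stopifnot(is.list(X), length(X) >= 1L)
  if (is.null(names(X))) names(X) <- paste0("omic", seq_along(X))
  for (nm in names(X)) {
    if (is.null(rownames(X[[nm]])))
      stop(sprintf("omic '%s' lacks observation row names", nm),
           call. = FALSE)
  }
  if (is.null(names(Y))) {
    if (length(Y) != nrow(X[[1L]]))
      stop("unnamed `Y` must align with the first omic matrix", call. = FALSE)
    names(Y) <- rownames(X[[1L]])
  }
  nms <- names(Y)
  Y <- factor(as.character(Y))
  names(Y) <- nms
  if (nlevels(Y) < 2) stop("`Y` needs at least two classes", call. = FALSE)
  structure(list(X = X, Y = Y), class = "multiomic_ml_data")
}

#' Common observations of an omic combination
#'
#' Intersects the observation identifiers of the selected omics, in sorted
#' (deterministic) order, and aligns all matrices and the class vector to
#' them.
#'
#' @param data A [multiomic_ml_data()] object.
#' @param combination Character vector of omic names (default: all).
#' @return List with `X` (aligned matrices), `Y`, `ids` and `N_max`.
#' @export
common_observations <- function(data, combination = names(data$X)) {
  stopifnot(inherits(data, "multiomic_ml_data"), length(combination) >= 1L)
  if (!all(combination %in% names(data$X)))
    stop("unknown omic in combination: ",
         paste(setdiff(combination, names(data$X)), collapse = ", "),
         call. = FALSE)
  ids <- Reduce(intersect, lapply(data$X[combination], rownames))
  ids <- intersect(ids, names(data$Y))
  ids <- sort(ids)
  Y <- droplevels(data$Y[ids])
  if (length(ids) < 2 || any(table(Y) < 2))
    stop("fewer than two common observations per class for this combination",
         call. = FALSE)
  list(X = lapply(data$X[combination], function(m) m[ids, , drop = FALSE]),
       Y = Y, ids = ids, N_max = length(ids))
}

#' Tick sizes of the learning curve
#'
#' Approximately evenly spaced subset sizes from two observations per class
#' up to `N_max`, deduplicated after rounding; a warning is emitted when the
#' range supports fewer distinct sizes than requested.
#'
#' @param N_max Total number of common observations.
#' @param n_ticks Requested number of ticks (>= 2).
#' @param n_classes Number of classes (sets the floor `2 * n_classes`).
#' @return Integer vector of strictly increasing sizes.
#' @export
make_ticks <- function(N_max, n_ticks = 5L, n_classes = 2L) {
  if (n_ticks < 2) stop("`n_ticks` must be >= 2", call. = FALSE)
  lo <- 2L * n_classes
  if (lo > N_max)
    stop(sprintf("N_max = %d is below the minimum subset size %d", N_max, lo),
         call. = FALSE)
  sizes <- unique(as.integer(round(seq(lo, N_max, length.out = n_ticks))))
  if (length(sizes) < n_ticks)
    warning(sprintf("only %d distinct tick sizes available between %d and %d",
                    length(sizes), lo, N_max), call. = FALSE)
  sizes
}

# stratified sample of `n` observation indices, keeping >= 2 per class when
# possible (proportional allocation, largest-remainder rounding)
stratified_sample <- function(Y, n) {
  lev <- levels(Y)
  n <- min(n, length(Y))
  tab <- table(Y)
  alloc <- pmax(round(n * as.numeric(tab) / length(Y)), 2L)
  alloc <- pmin(alloc, as.numeric(tab))
  # adjust to hit n exactly
  while (sum(alloc) > n) {
    j <- which.max(alloc)
    if (alloc[j] <= 2L) break
    alloc[j] <- alloc[j] - 1L
  }
  while (sum(alloc) < n) {
    room <- as.numeric(tab) - alloc
    j <- which.max(room)
    if (room[j] <= 0) break
    alloc[j] <- alloc[j] + 1L
  }
  idx <- unlist(lapply(seq_along(lev), function(j) {
    pool <- which(Y == lev[j])
    sample(pool, alloc[j])
  }))
  sort(idx)
}

#' LASSO-based variable selection for a multi-omic subset
#'
#' Runs the LASSO regularization path (binomial or multinomial deviance,
#' penalty chosen by internal cross-validation) on repeated random
#' subsamples of the observations and keeps the variables selected in at
#' least `freq` of the repeats; if that set is empty, the union over
#' repeats is used. Variables are addressed as `omic.variable` across the
#' concatenated blocks.
#'
#' @param X List of aligned omic matrices (observations x variables).
#' @param Y Class factor aligned with the rows.
#' @param n Observations drawn per repeat (default: all rows).
#' @param reps Number of selection repeats (default 15).
#' @param freq Selection-frequency threshold (default 0.5).
#' @return Character vector of selected variable names (length >= 1).
#' @export
select_variables <- function(X, Y, n = nrow(X[[1L]]), reps = 15L,
                             freq = 0.5) {
  Xw <- do.call(cbind, lapply(names(X), function(nm) {
    m <- X[[nm]]
    colnames(m) <- paste(nm, colnames(m) %||% seq_len(ncol(m)), sep = ".")
    m
  }))
  fam <- if (nlevels(droplevels(Y)) == 2) "binomial" else "multinomial"
  counts <- integer(ncol(Xw))
  names(counts) <- colnames(Xw)
  got <- 0L
  for (r in seq_len(reps)) {
    sel <- NULL
    for (try in 1:5) {  # resample if a class drops out of the subsample
      idx <- stratified_sample(Y, n)
      if (nlevels(droplevels(Y[idx])) >= 2) { sel <- idx; break }
    }
    if (is.null(sel))
      stop("could not draw a subsample containing every class", call. = FALSE)
    ycl <- droplevels(Y[sel])
    # glmnet warns about small class counts at every small tick; that is the
    # expected operating regime of a learning curve, so silence just that
    quiet_small <- function(expr)
      withCallingHandlers(expr, warning = function(w) {
        if (grepl("fewer than 8|dangerous ground|too small|grouped=FALSE",
                  conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    cf <- tryCatch(quiet_small({
      if (min(table(ycl)) >= 3L) {
        # penalty strength by internal cross-validation
        nf <- max(3L, min(5L, min(table(ycl))))
        fit <- glmnet::cv.glmnet(Xw[sel, , drop = FALSE], ycl, family = fam,
                                 alpha = 1, nfolds = nf)
        stats::coef(fit, s = "lambda.min")
      } else {
        # too few observations per class to cross-validate: take the path
        # point whose support size is about half the subset size
        fit <- glmnet::glmnet(Xw[sel, , drop = FALSE], ycl, family = fam,
                              alpha = 1)
        target <- max(1L, floor(length(sel) / 2))
        s_pick <- fit$lambda[which.min(abs(fit$df - target))]
        stats::coef(fit, s = s_pick)
      }
    }), error = function(e) NULL)
    if (is.null(cf)) next
    nz <- if (is.list(cf)) {
      unique(unlist(lapply(cf, function(m) rownames(m)[m[, 1L] != 0])))
    } else rownames(cf)[cf[, 1L] != 0]
    nz <- setdiff(nz, "(Intercept)")
    counts[nz] <- counts[nz] + 1L
    got <- got + 1L
  }
  if (got == 0L)
    stop("LASSO selection failed in every repeat", call. = FALSE)
  chosen <- names(counts)[counts >= freq * got]
  if (length(chosen) == 0L) chosen <- names(counts)[counts > 0L]
  if (length(chosen) == 0L) {
    # no signal anywhere on the path: keep the first variables to enter the
    # regularization path so downstream evaluation still runs (and reports
    # a chance-level error on genuinely uninformative data)
    fit <- glmnet::glmnet(Xw, droplevels(Y), family = fam, alpha = 1)
    first <- which(fit$df > 0)[1L]
    if (!is.na(first)) {
      cf <- stats::coef(fit, s = fit$lambda[first])
      nz <- if (is.list(cf)) {
        unique(unlist(lapply(cf, function(m) rownames(m)[m[, 1L] != 0])))
      } else rownames(cf)[cf[, 1L] != 0]
      chosen <- setdiff(nz, "(Intercept)")
    }
  }
  if (length(chosen) == 0L)
    stop("LASSO selected no variables; the data may carry no class signal",
         call. = FALSE)
  chosen
}

subset_blocks <- function(X, vars) {
  out <- lapply(names(X), function(nm) {
    cols <- sub(paste0("^", nm, "\\."), "",
                grep(paste0("^", nm, "\\."), vars, value = TRUE))
    m <- X[[nm]]
    if (is.null(colnames(m))) colnames(m) <- seq_len(ncol(m))
    m[, colnames(m) %in% cols, drop = FALSE]
  })
  names(out) <- names(X)
  out[vapply(out, ncol, integer(1)) > 0L]
}

# classification error of one train/evaluate round
classifier_error <- function(X, Y, ml, cv, balanced = FALSE, ntree = 500L,
                             H = 3L, distance = "centroid") {
  if (ml == "rf") {
    Xw <- do.call(cbind, X)
    if (cv == "oob") {
      fit <- randomForest::randomForest(Xw, Y, ntree = ntree)
      pred <- fit$predicted   # OOB predictions
    } else {
      pred <- cv_predict(Xw, Y, cv, function(tr, te)
        as.character(stats::predict(
          randomForest::randomForest(Xw[tr, , drop = FALSE], Y[tr],
                                     ntree = ntree),
          Xw[te, , drop = FALSE])))
    }
  } else {
    if (cv == "oob")
      stop("OOB error is only defined for the random forest", call. = FALSE)
    pred <- cv_predict(NULL, Y, cv, function(tr, te) {
      fits <- lapply(X, function(m) plsda_fit(m[tr, , drop = FALSE], Y[tr],
                                              H = H))
      # average the matrix-form PLS predictions over blocks, then apply the
      prs <- lapply(seq_along(X), function(o) {
        f <- fits[[o]]
        Xs <- sweep(sweep(X[[o]][te, , drop = FALSE], 2L, f$center), 2L,
                    f$scale, "/")
        pls_predict(Xs, f$W, f$D, f$B)
      })
      Hmin <- min(vapply(prs, function(p) ncol(p$Tpred), integer(1)))
      Yh <- Reduce(`+`, lapply(prs, `[[`, "Yhat")) / length(prs)
      Tp <- Reduce(`+`, lapply(prs, function(p)
        p$Tpred[, seq_len(Hmin), drop = FALSE])) / length(prs)
      ref <- fits[[1L]]
      ref$scores <- Reduce(`+`, lapply(fits, function(f)
        f$scores[, seq_len(Hmin), drop = FALSE])) / length(fits)
      as.character(assign_class(list(Yhat = Yh, Tpred = Tp), ref, distance))
    })
  }
  pred <- factor(as.character(pred), levels = levels(Y))
  if (balanced) {
    per <- vapply(levels(Y), function(l)
      mean(pred[Y == l] != l), numeric(1))
    mean(per, na.rm = TRUE)
  } else {
    mean(pred != Y)
  }
}

# generic CV driver returning per-observation predictions (character)
cv_predict <- function(Xw, Y, cv, fit_predict) {
  n <- length(Y)
  pred <- character(n)
  if (cv == "loo") {
    folds <- as.list(seq_len(n))
  } else {
    k <- min(10L, n)
    # stratified folds; refold guards against single-class training sets
    folds <- NULL
    for (try in 1:10) {
      f <- unsplit(lapply(split(seq_len(n), Y), function(ix)
        sample(rep_len(seq_len(k), length(ix)))), Y)
      cand <- split(seq_len(n), f)
      ok <- all(vapply(cand, function(te)
        nlevels(droplevels(Y[-te])) >= 2, logical(1)))
      if (ok) { folds <- cand; break }
    }
    if (is.null(folds)) folds <- as.list(seq_len(n))  # fall back to LOO
  }
  for (te in folds) {
    tr <- setdiff(seq_len(n), te)
    pred[te] <- fit_predict(tr, te)
  }
  pred
}

tick_seed <- function(seed, size, iter) {
  as.integer((as.numeric(seed) * 7919 + size * 104729 + iter * 7907) %%
               2147483647)
}

#' Mean classification error at one tick
#'
#' One tick of the learning curve: `m` times, a stratified subset of size
#' `n_t` is drawn for LASSO variable selection (itself repeated `sel_reps`
#' times on subsamples), a fresh subset of the same size is drawn, and the
#' classification error of the chosen learner is computed on it with the
#' chosen validation scheme (out-of-bag for the random forest, stratified
#' ten-fold, or leave-one-out). The returned summary carries the mean error
#' and a normal-approximation 95% confidence interval over the iterations.
#'
#' @param X List of aligned omic matrices.
#' @param Y Class factor.
#' @param n_t Subset size (total observations).
#' @param ml `"rf"` or `"plsda"`.
#' @param cv `"oob"` (rf only), `"tenfold"` or `"loo"`.
#' @param m Iterations per tick (default 15).
#' @param sel_reps LASSO repeats per selection (default 15).
#' @param balanced Report the balanced (macro-averaged) error?
#' @param ntree Random-forest trees (default 500).
#' @param H PLS-DA components (default 3).
#' @param distance PLS-DA/assignment distance rule.
#' @param seed Base seed; iteration seeds are derived from `(seed, n_t)` so
#'   results for a tick are reproducible regardless of evaluation order.
#' @return List with `n`, `er` (mean), `se`, `ci` (length 2), `iters`.
#' @export
evaluate_tick <- function(X, Y, n_t, ml = c("rf", "plsda"),
                          cv = c("oob", "tenfold", "loo"), m = 15L,
                          sel_reps = 15L, balanced = FALSE, ntree = 500L,
                          H = 3L, distance = "centroid", seed = 1L) {
  ml <- match.arg(ml)
  cv <- match.arg(cv)
  if (cv == "oob" && ml != "rf")
    stop("OOB error is only available with ml = \"rf\"", call. = FALSE)
  ers <- numeric(m)
  for (it in seq_len(m)) {
    set.seed(tick_seed(seed, n_t, it))
    i_sel <- stratified_sample(Y, n_t)
    vars <- select_variables(lapply(X, function(mm) mm[i_sel, , drop = FALSE]),
                             Y[i_sel], n = length(i_sel), reps = sel_reps)
    i_eval <- stratified_sample(Y, n_t)
    Xe <- subset_blocks(lapply(X, function(mm) mm[i_eval, , drop = FALSE]),
                        vars)
    ers[it] <- classifier_error(Xe, droplevels(Y[i_eval]), ml, cv,
                                balanced = balanced, ntree = ntree, H = H,
                                distance = distance)
  }
  se <- if (m > 1) stats::sd(ers) / sqrt(m) else 0
  list(n = n_t, er = mean(ers), se = se,
       ci = mean(ers) + c(-1, 1) * 1.96 * se, iters = ers)
}

#' Fit the learning curve through the tick errors
#'
#' Smooths mean classification error against subset size with a first-order
#' penalized P-spline ([fit_pspline()]); the effective degrees of freedom
#' are the number of ticks minus one. If confidence-interval half-widths
#' are supplied, an upper-bound curve is fitted with the same smoothing
#' parameter for the margin-of-error computation.
#'
#' @param ticks Integer vector of tick sizes (>= 3).
#' @param er Mean error rate at each tick.
#' @param ci_half Optional CI half-width at each tick.
#' @param df Effective degrees of freedom (default `length(ticks) - 1`).
#' @return An object of class `learning_curve`.
#' @export
fit_learning_curve <- function(ticks, er, ci_half = NULL,
                               df = length(ticks) - 1) {
  if (length(ticks) < 3) stop("need at least 3 ticks", call. = FALSE)
  stopifnot(length(er) == length(ticks))
  fit <- fit_pspline(ticks, er, df = df)
  upper <- NULL
  if (!is.null(ci_half)) {
    stopifnot(length(ci_half) == length(ticks))
    up <- fit_pspline(ticks, er + ci_half, df = df)
    upper <- up
  }
  structure(list(ticks = ticks, er = er, ci_half = ci_half, fit = fit,
                 upper = upper, df = df),
            class = "learning_curve")
}

#' @export
predict.learning_curve <- function(object, newdata, ...) {
  stats::predict(object$fit, newdata)
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("<learning_curve> %d ticks (n = %d..%d), ER %.3f..%.3f, edf %.2f\n",
              length(x$ticks), min(x$ticks), max(x$ticks),
              max(x$er), min(x$er), x$fit$edf))
  invisible(x)
}

#' Predicted sample size for a target error rate
#'
#' Evaluates the fitted learning curve on the integer grid from the
#' smallest tick to `cap` (default ten times the largest tick,
#' extrapolating linearly beyond it) and returns the smallest sample size
#' whose predicted error is at or below `er_target`. The margin of error
#' (MOE) is the distance, in samples, between that crossing and the
#' crossing of the upper-confidence curve; it is `NA` when the curve was
#' fitted without confidence intervals, and the result is flagged
#' unreachable when even the capped extrapolation stays above the target.
#'
#' @param curve A [fit_learning_curve()] object.
#' @param er_target Target classification error, > 0.
#' @param cap Largest sample size considered (default `10 * max(ticks)`).
#' @return List with `pss`, `moe`, `reachable`, `er_target`.
#' @export
predict_sample_size <- function(curve, er_target,
                                cap = 10L * max(curve$ticks)) {
  stopifnot(inherits(curve, "learning_curve"))
  if (!is.numeric(er_target) || er_target < 0)
    stop("`er_target` must be non-negative", call. = FALSE)
  grid <- seq.int(max(2L, min(curve$ticks)), cap)
  pred <- stats::predict(curve$fit, grid)
  hit <- which(pred <= er_target)
  if (length(hit) == 0L)
    return(list(pss = NA_integer_, moe = NA_real_, reachable = FALSE,
                er_target = er_target))
  pss <- grid[hit[1L]]
  moe <- NA_real_
  if (!is.null(curve$upper)) {
    predu <- stats::predict(curve$upper, grid)
    hitu <- which(predu <= er_target)
    moe <- if (length(hitu)) abs(grid[hitu[1L]] - pss) else Inf
  }
  list(pss = as.integer(pss), moe = moe, reachable = TRUE,
       er_target = er_target)
}

# stop rule: on a shared n-grid, do the last three fitted curves agree
# (within `tol` absolute ER) on at least `share` of the grid?
curves_converged <- function(fits, grid, share = 0.12, tol = 0.005) {
  preds <- vapply(fits, function(f) stats::predict(f$fit, grid),
                  numeric(length(grid)))
  spread <- apply(preds, 1L, function(z) max(z) - min(z))
  mean(spread <= tol) >= share
}

#' Learning-curve sample-size estimation for a multi-omic classifier
#'
#' The full pipeline: align the omics of the requested combination on their
#' common observations; evaluate classification error on an increasing
#' number of subset sizes (ticks), starting from 5 ticks and adding one at
#' a time; after each addition fit the penalized-spline learning curve and
#' stop once three consecutive fits agree on at least 12% of a common
#' sample-size grid (within 0.005 absolute error) or the tick budget is
#' exhausted; finally invert the curve at the target error rate. When
#' `er_target` is not given, the error observed at the full pilot size
#' (largest tick) is used.
#'
#' Tick evaluations are cached by subset size, so enlarging the tick set
#' reuses earlier work; with a fixed `seed` the whole run is reproducible.
#'
#' @param data A [multiomic_ml_data()] object.
#' @param combination Omic names to use (default all).
#' @param ml,cv,m,sel_reps,balanced,ntree,H,distance As [evaluate_tick()].
#' @param er_target Target error rate (default: pilot error).
#' @param ticks_init Initial number of ticks (default 5).
#' @param tick_cap Maximum number of ticks (default 12).
#' @param seed Mandatory integer seed.
#' @return An object of class `multiml_result`: tick table, fitted
#'   `learning_curve`, `pss`, `moe`, `er_target`, `N_max`, `converged`.
#' @export
multiml <- function(data, combination = names(data$X), ml = c("rf", "plsda"),
                    cv = c("oob", "tenfold", "loo"), er_target = NULL,
                    m = 15L, sel_reps = 15L, balanced = FALSE, ntree = 500L,
                    H = 3L, distance = "centroid", ticks_init = 5L,
                    tick_cap = 12L, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  ml <- match.arg(ml)
  cv <- match.arg(cv)
  co <- common_observations(data, combination)
  n_classes <- nlevels(co$Y)
  cache <- new.env(parent = emptyenv())
  eval_size <- function(sz) {
    key <- as.character(sz)
    if (is.null(cache[[key]]))
      cache[[key]] <- evaluate_tick(co$X, co$Y, sz, ml = ml, cv = cv, m = m,
                                    sel_reps = sel_reps, balanced = balanced,
                                    ntree = ntree, H = H, distance = distance,
                                    seed = seed)
    cache[[key]]
  }
  fits <- list()
  converged <- FALSE
  n_ticks <- ticks_init
  repeat {
    sizes <- make_ticks(co$N_max, n_ticks, n_classes)
    res <- lapply(sizes, eval_size)
    er <- vapply(res, `[[`, numeric(1), "er")
    ci_half <- vapply(res, function(r) 1.96 * r$se, numeric(1))
    if (length(sizes) >= 3) {
      fits[[length(fits) + 1L]] <-
        fit_learning_curve(sizes, er, ci_half = ci_half)
    }
    if (length(fits) >= 3) {
      grid <- seq(min(sizes), co$N_max, length.out = 100)
      last3 <- fits[seq(length(fits) - 2L, length(fits))]
      if (curves_converged(last3, grid)) { converged <- TRUE; break }
    }
    if (n_ticks >= tick_cap || length(sizes) >= co$N_max - 2 * n_classes + 1) {
      if (length(fits) >= 3 && !converged)
        warning("tick budget exhausted before the stop rule was met",
                call. = FALSE)
      break
    }
    n_ticks <- n_ticks + 1L
  }
  curve <- fits[[length(fits)]]
  if (is.null(er_target)) er_target <- curve$er[length(curve$er)]
  ps <- predict_sample_size(curve, er_target)
  tick_table <- data.frame(n = curve$ticks, er = curve$er,
                           ci_half = curve$ci_half)
  structure(list(combination = combination, ticks = tick_table,
                 curve = curve, pss = ps$pss, moe = ps$moe,
                 reachable = ps$reachable, er_target = er_target,
                 N_max = co$N_max, converged = converged,
                 settings = list(ml = ml, cv = cv, m = m,
                                 sel_reps = sel_reps, ntree = ntree, H = H,
                                 distance = distance, seed = seed)),
            class = "multiml_result")
}

#' @export
print.multiml_result <- function(x, ...) {
  cat(sprintf("<multiml_result> omics: %s  (N_max = %d)\n",
              paste(x$combination, collapse = "+"), x$N_max))
  print(x$ticks, row.names = FALSE, digits = 3)
  if (x$reachable)
    cat(sprintf("predicted sample size for ER <= %.3g: %d (MOE %s)\n",
                x$er_target, x$pss, format(x$moe)))
  else
    cat(sprintf("target ER %.3g not reachable within the extrapolation cap\n",
                x$er_target))
  invisible(x)
}

#' Compare omic combinations by predicted sample size
#'
#' Runs [multiml()] for each requested combination and tabulates the
#' predicted sample size and margin of error, to identify the most
#' informative (or most economical) set of platforms.
#'
#' @param data A [multiomic_ml_data()] object.
#' @param combinations List of character vectors of omic names.
#' @param er_target Target error rate shared by all runs.
#' @param ... Passed to [multiml()] (including the mandatory `seed`).
#' @return A data frame with one row per combination, with the full
#'   results attached as attribute `runs`.
#' @export
compare_combinations <- function(data, combinations, er_target, ...) {
  runs <- lapply(combinations, function(cmb)
    multiml(data, combination = cmb, er_target = er_target, ...))
  out <- data.frame(
    combination = vapply(combinations, paste, character(1), collapse = "+"),
    n_omics = lengths(combinations),
    N_max = vapply(runs, `[[`, integer(1), "N_max"),
    pss = vapply(runs, function(r)
      if (r$reachable) r$pss else NA_integer_, integer(1)),
    moe = vapply(runs, `[[`, numeric(1), "moe"),
    reachable = vapply(runs, `[[`, logical(1), "reachable"),
    stringsAsFactors = FALSE)
  attr(out, "runs") <- runs
  out
}

#' Partition tick evaluations into independent jobs
#'
#' Helper for users running on a scheduler: the `(tick size, iteration)`
#' pairs of a [multiml()] run are independent given the seed, so they can
#' be evaluated in parallel and combined. Each row carries the derived seed
#' that [evaluate_tick()] would use, making distributed results identical
#' to a serial run.
#'
#' @param ticks Integer vector of tick sizes.
#' @param m Iterations per tick.
#' @param seed Base seed of the run.
#' @return Data frame with columns `tick`, `iter`, `seed`.
#' @export
multiml_jobs <- function(ticks, m, seed) {
  jobs <- expand.grid(tick = ticks, iter = seq_len(m))
  jobs$seed <- mapply(tick_seed, seed, jobs$tick, jobs$iter)
  jobs[order(jobs$tick, jobs$iter), ]
}

#' Plot a fitted learning curve
#'
#' Error rate against sample size with the tick means, their confidence
#' intervals, the penalized-spline fit (extended to the predicted sample
#' size), the target error rate and the PSS marker.
#'
#' @param result A `multiml_result`.
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(result) {
  stopifnot(inherits(result, "multiml_result"))
  upper <- if (result$reachable) max(result$pss, result$N_max) else
    max(result$ticks$n)
  grid <- seq(min(result$ticks$n), upper, length.out = 200)
  df_fit <- data.frame(n = grid, er = stats::predict(result$curve, grid))
  p <- ggplot2::ggplot(result$ticks, ggplot2::aes(x = .data$n, y = .data$er)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$er - .data$ci_half,
                                        ymax = .data$er + .data$ci_half),
                           width = 0.3, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = df_fit, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = result$er_target, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "number of samples", y = "classification error rate") +
    ggplot2::theme_bw()
  if (result$reachable)
    p <- p + ggplot2::annotate("point", x = result$pss, y = result$er_target,
                               shape = 17, size = 3, colour = "firebrick")
  p
}
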