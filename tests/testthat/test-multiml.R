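test_that("common observations are the sorted identifier intersection", {
  X1 <- matrix(rnorm(40 * 3), 40, 3,
               dimnames = list(sprintf("S%02d", 1:40), NULL))
  X2 <- matrix(rnorm(35 * 3), 35, 3,
               dimnames = list(sprintf("S%02d", 6:40), NULL))
  Y <- setNames(rep(c("a", "b"), 20), sprintf("S%02d", 1:40))
  d <- multiomic_ml_data(list(one = X1, two = X2), Y)
  co <- common_observations(d)
  expect_equal(co$N_max, 35)
  expect_identical(co$ids, sort(sprintf("S%02d", 6:40)))
  expect_identical(rownames(co$X$one), co$ids)
  # identical id sets: everything kept
  co1 <- common_observations(d, "one")
  expect_equal(co1$N_max, 40)
  # disjoint sets: error
  X3 <- matrix(rnorm(9), 3, 3, dimnames = list(c("Z1", "Z2", "Z3"), NULL))
  d2 <- multiomic_ml_data(list(one = X1, three = X3), Y)
  expect_error(common_observations(d2), "common observations")
  expect_error(common_observations(d, "nope"), "unknown omic")
})

test_that("tick sizes run from two per class to N_max, deduplicated", {
  expect_identical(make_ticks(10, 5, 2), c(4L, 6L, 7L, 8L, 10L))
  t2 <- make_ticks(40, 5, 2)
  expect_identical(t2[1], 4L)
  expect_identical(t2[length(t2)], 40L)
  expect_true(all(diff(t2) > 0))
  # approximately even spacing
  expect_lte(max(abs(diff(t2) - (40 - 4) / 4)), 1)
  expect_warning(t3 <- make_ticks(8, 10, 2), "distinct")
  expect_lt(length(t3), 10)
  expect_error(make_ticks(3, 5, 2), "below the minimum")
})

test_that("LASSO selection recovers planted informative variables", {
  hits <- 0L
  for (seed in 1:5) {
    d <- gen_ml_dataset(n_per_class = 30, omics = 1, p = 40, informative = 3,
                        separation = 3, seed = seed)
    set.seed(seed)
    sel <- select_variables(d$X, d$Y, reps = 7)
    planted <- paste0("omic1.", attr(d, "truth")$omic1)
    if (all(planted %in% sel)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("all-noise data still yields a usable (small) selection", {
  d <- gen_ml_dataset(n_per_class = 20, omics = 1, p = 30, informative = 0,
                      separation = 0, seed = 3)
  set.seed(3)
  sel <- select_variables(d$X, d$Y, reps = 5)
  expect_gte(length(sel), 1L)
  expect_lt(length(sel), 30L)
})

test_that("PLS predictions equal the direct matrix-algebra computation", {
  # hand-built small matrices: one new row through the matrix-form predictor
  W <- matrix(c(0.5, 0.1, -0.3, 0.2, 0.4, 0.6), 3, 2)
  D <- matrix(c(0.45, 0.12, -0.25, 0.15, 0.35, 0.55), 3, 2)
  B <- matrix(c(1.2, -0.7, 0.3, 0.9), 2, 2)
  xnew <- matrix(c(0.3, -1.1, 0.7), 1, 3)
  pr <- pls_predict(xnew, W, D, B)
  expect_equal(pr$Yhat, xnew %*% W %*% solve(t(D) %*% W) %*% B,
               tolerance = 1e-12)
  expect_equal(pr$Tpred, xnew %*% W %*% solve(t(D) %*% W),
               tolerance = 1e-12)
  # random instances from fitted models agree to 1e-10
  set.seed(9)
  for (rep in 1:5) {
    N <- sample(10:20, 1); P <- sample(4:8, 1); H <- sample(2:3, 1)
    X <- matrix(rnorm(N * P), N, P)
    Y <- factor(rep_len(c("a", "b", "c"), N))
    fit <- plsda_fit(X, Y, H = H)
    Xs <- sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
    pr <- pls_predict(Xs, fit$W, fit$D, fit$B)
    direct <- Xs %*% fit$W %*% solve(t(fit$D) %*% fit$W) %*% fit$B
    expect_lt(max(abs(pr$Yhat - direct)), 1e-10)
  }
})

test_that("PLS-DA separates well-separated classes with every distance rule", {
  d <- gen_ml_dataset(n_per_class = 20, omics = 1, p = 15, informative = 4,
                      separation = 3, seed = 12)
  X <- d$X$omic1
  fit <- plsda_fit(X, d$Y, H = 2)
  for (dist in c("centroid", "maximum", "mahalanobis")) {
    pred <- predict(fit, X, distance = dist)
    expect_lt(mean(pred != d$Y), 0.1)
  }
})

test_that("tick evaluation: separable data near zero, permuted labels at chance", {
  d <- gen_ml_dataset(n_per_class = 20, omics = 1, p = 20, informative = 4,
                      separation = 3, seed = 21)
  res <- evaluate_tick(d$X, d$Y, n_t = 20, ml = "rf", cv = "oob", m = 4,
                       sel_reps = 4, ntree = 200, seed = 5)
  expect_lt(res$er, 0.15)
  set.seed(99)
  Yperm <- setNames(sample(as.character(d$Y)), names(d$Y))
  dperm <- multiomic_ml_data(d$X, Yperm)
  resp <- evaluate_tick(dperm$X, dperm$Y, n_t = 30, ml = "rf", cv = "oob",
                        m = 6, sel_reps = 4, ntree = 200, seed = 6)
  # chance level for balanced two-class labels, with a binomial-style band
  expect_gt(resp$er, 0.3)
  expect_lt(resp$er, 0.7)
  expect_true(resp$ci[1] <= resp$er && resp$er <= resp$ci[2])
  expect_error(evaluate_tick(d$X, d$Y, 10, ml = "plsda", cv = "oob",
                             seed = 1), "rf")
})

test_that("learning-curve prediction inverts an analytic error curve", {
  ticks <- seq(4, 60, length.out = 10)
  er <- 0.5 * exp(-ticks / 20)
  lc <- fit_learning_curve(ticks, er, ci_half = rep(0.01, 10))
  ps <- predict_sample_size(lc, er_target = 0.1)
  expect_true(ps$reachable)
  expect_lt(abs(ps$pss - 20 * log(5)), 2.5)
  expect_true(is.finite(ps$moe))
  # target above the curve start: smallest tick returned
  ps2 <- predict_sample_size(lc, er_target = 0.6)
  expect_identical(ps2$pss, 4L)
  # flat curve above the target: unreachable
  flat <- fit_learning_curve(ticks, rep(0.4, 10))
  ps3 <- predict_sample_size(flat, er_target = 0.1)
  expect_false(ps3$reachable)
  expect_error(fit_learning_curve(c(4, 10), c(0.3, 0.2)), "3 ticks")
})

test_that("full runs are reproducible and terminate on smooth curves", {
  d <- gen_ml_dataset(n_per_class = 22, omics = 2, p = 25, informative = 4,
                      separation = 2.5, seed = 41)
  r1 <- multiml(d, m = 3, sel_reps = 3, ntree = 100, tick_cap = 9, seed = 7)
  r2 <- multiml(d, m = 3, sel_reps = 3, ntree = 100, tick_cap = 9, seed = 7)
  expect_identical(r1$ticks, r2$ticks)
  expect_identical(r1$pss, r2$pss)
  expect_true(r1$converged)
  # error rates are non-increasing up to CI noise on separable data
  er <- r1$ticks$er
  iso <- stats::isoreg(r1$ticks$n, -er)
  resid <- abs(-iso$yf - er)
  band <- pmax(2 * r1$ticks$ci_half, 0.05)
  expect_true(all(resid <= band + 1e-9))
})

test_that("seed requirement and job partitioning are honored", {
  d <- gen_ml_dataset(n_per_class = 10, seed = 1)
  expect_error(multiml(d, m = 1), "seed")
  jobs <- multiml_jobs(c(4, 10, 16), m = 3, seed = 5)
  expect_identical(nrow(jobs), 9L)
  expect_identical(unique(jobs$tick), c(4, 10, 16))
  # derived seeds are deterministic and distinct across ticks/iterations
  expect_identical(jobs$seed, multiml_jobs(c(4, 10, 16), 3, 5)$seed)
  expect_false(any(duplicated(jobs$seed)))
})

test_that("single-combination comparison equals the direct run", {
  d <- gen_ml_dataset(n_per_class = 15, omics = 2, p = 15, informative = 3,
                      separation = 2.5, seed = 51)
  direct <- multiml(d, combination = c("omic1"), m = 2, sel_reps = 3,
                    ntree = 80, tick_cap = 5, er_target = 0.1, seed = 3)
  cmp <- compare_combinations(d, list(c("omic1")), er_target = 0.1, m = 2,
                              sel_reps = 3, ntree = 80, tick_cap = 5,
                              seed = 3)
  expect_identical(nrow(cmp), 1L)
  expect_identical(cmp$pss, direct$pss)
  expect_identical(cmp$N_max, direct$N_max)
})
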