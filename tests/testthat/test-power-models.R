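test_that("t-test power matches direct noncentral-t quadrature", {
  cases <- expand.grid(n = c(3, 8, 16, 40), alpha = c(0.01, 0.05),
                       d = c(0.5, 1, 1.5))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    got <- power_normal(cs$n, cs$alpha, normal_params(cs$d, 1))
    expect_equal(got, oracle_t_power(cs$n, cs$alpha, cs$d, 1),
                 tolerance = 1e-6)
  }
  # delta/sigma enter only through their ratio times the scale
  expect_equal(power_normal(8, 0.05, normal_params(2.2, 1.1)),
               oracle_t_power(8, 0.05, 2, 1), tolerance = 1e-6)
})

test_that("null effects give power equal to the significance level", {
  expect_equal(power_normal(10, 0.05, normal_params(0, 1)), 0.05)
  expect_equal(power_binary(20, 0.05, binary_params(0.3, 0.3)), 0.05)
  for (a in c(0.01, 0.05, 0.1)) {
    pw <- power_count(10, a, count_params(0.5, 30, omega = 1, w = 1))
    expect_lt(abs(pw - a), 0.01)
  }
})

test_that("large-sample t power approaches the z-test closed form", {
  n <- 5000
  got <- power_normal(n, 0.05, normal_params(0.05, 1))
  expect_equal(got, oracle_z_power(n, 0.05, 0.05, 1), tolerance = 1e-3)
})

test_that("proportion power matches the closed-form expression and is symmetric", {
  expect_equal(power_binary(20, 0.05, binary_params(0.2, 0.8)),
               oracle_prop_power(20, 0.05, 0.2, 0.8), tolerance = 1e-8)
  grid <- expand.grid(pA = c(0.1, 0.3, 0.45), pB = c(0.5, 0.7, 0.9),
                      n = c(5, 25))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_equal(power_binary(g$n, 0.05, binary_params(g$pA, g$pB)),
                 power_binary(g$n, 0.05, binary_params(g$pB, g$pA)))
  }
})

test_that("power is monotone in sample size for every data type", {
  set.seed(42)
  ns <- c(2, 3, 5, 8, 13, 21, 34, 55, 89, 144, 200)
  for (rep in 1:5) {
    pn <- normal_params(runif(1, 0.2, 2), runif(1, 0.3, 2))
    expect_true(all(diff(power_normal(ns, 0.05, pn)) >= 0))
    pb <- binary_params(runif(1, 0.05, 0.45), runif(1, 0.5, 0.95))
    expect_true(all(diff(power_binary(ns, 0.05, pb)) >= 0))
  }
  # exact-test discreteness can produce sub-1e-3 local wiggles
  for (rep in 1:2) {
    pc <- count_params(runif(1, 0.1, 0.8), runif(1, 10, 40),
                       runif(1, 1.3, 2.5))
    pw <- power_count(c(2, 4, 8, 12, 16), 0.05, pc)
    expect_true(all(diff(pw) >= -2e-3))
  }
})

test_that("count power: Poisson limit and exact/approximate agreement", {
  # phi = 0 runs through the Poisson branch and behaves like an exact test
  pw0 <- power_count(6, 0.05, count_params(0, 20, omega = 2))
  expect_gt(pw0, 0.5)
  expect_lt(abs(power_count(6, 0.05, count_params(0, 20, omega = 1)) - 0.05),
            0.015)
  # in the moderate-count regime the normal approximation tracks the exact
  pars <- count_params(0.3, 60, omega = 1.8)
  ex <- power_count(12, 0.01, pars, method = "exact")
  ap <- power_count(12, 0.01, pars, method = "approx")
  expect_lt(abs(ex - ap), 0.03)
})

test_that("minimum sample size equals the brute-force scan", {
  set.seed(7)
  for (rep in 1:60) {
    p <- normal_params(runif(1, 0.3, 2), runif(1, 0.3, 2))
    a <- runif(1, 0.005, 0.1)
    tgt <- runif(1, 0.3, 0.95)
    got <- min_sample_size(p, a, tgt, n_max = 60)
    exp_n <- oracle_min_n(function(n) power_normal(n, a, p), tgt, 60)
    if (is.na(exp_n)) expect_false(got$feasible)
    else expect_identical(got$n, exp_n)
  }
  for (rep in 1:40) {
    p <- binary_params(runif(1, 0.05, 0.4), runif(1, 0.5, 0.95))
    tgt <- runif(1, 0.3, 0.95)
    got <- min_sample_size(p, 0.05, tgt, n_max = 60)
    exp_n <- oracle_min_n(function(n) power_binary(n, 0.05, p), tgt, 60)
    if (is.na(exp_n)) expect_false(got$feasible)
    else expect_identical(got$n, exp_n)
  }
  # count data: a couple of draws in the exact regime
  for (rep in 1:3) {
    p <- count_params(runif(1, 0.2, 0.6), runif(1, 10, 30),
                      runif(1, 1.5, 2.5))
    got <- min_sample_size(p, 0.05, 0.8, n_max = 25)
    exp_n <- oracle_min_n(function(n) power_count(n, 0.05, p), 0.8, 25)
    if (is.na(exp_n)) expect_false(got$feasible)
    else expect_identical(got$n, exp_n)
  }
})

test_that("minimum sample size floors at 2 and flags infeasibility", {
  p <- normal_params(5, 0.5)
  expect_identical(min_sample_size(p, 0.05, 0.3)$n, 2L)
  weak <- normal_params(0.01, 1)
  res <- min_sample_size(weak, 0.01, 0.9, n_max = 50)
  expect_false(res$feasible)
  expect_true(is.na(res$n))
})

test_that("effect-size measures follow their definitions", {
  expect_equal(cohens_d(1.16, 1.05), 1.16 / 1.05)
  expect_equal(cohens_d(0, 2), 0)
  expect_equal(cohens_d(0.8 * 1.7, 1.7), 0.8)
  expect_equal(cohens_h(0.5, 0.5), 0)
  expect_equal(cohens_h(0.25, 0.75),
               2 * (asin(sqrt(0.75)) - asin(sqrt(0.25))))
  expect_equal(cohens_h(1, 0), pi)
  g <- expand.grid(a = c(0.1, 0.4, 0.9), b = c(0.2, 0.6))
  expect_equal(cohens_h(g$a, g$b), cohens_h(g$b, g$a))
})

test_that("invalid arguments are rejected", {
  expect_error(normal_params(-1, 1), "delta")
  expect_error(normal_params(1, 0), "sigma")
  expect_error(count_params(-0.1, 30, 2), "phi")
  expect_error(binary_params(1.2, 0.5), "proportions")
  expect_error(power_normal(1, 0.05, normal_params(1, 1)), "n")
  expect_error(power_normal(8, 1.2, normal_params(1, 1)), "alpha")
  expect_error(cohens_d(1, -2), "sigma")
  expect_error(cohens_h(-0.1, 0.5), "proportions")
  expect_error(min_sample_size(normal_params(1, 1), 0.05, 1.5), "target_power")
})
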