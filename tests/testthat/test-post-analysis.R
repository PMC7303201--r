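test_that("power curves equal pointwise power calls and handle the null", {
  o <- mk_omic("a", 1.3, 1.1)
  cur <- power_vs_n(o, n_range = 2:20)
  expect_equal(cur$power,
               omic_power(o$params, 2:20, o$alpha_star))
  expect_true(all(diff(cur$power) >= 0))
  null <- mk_omic("null", 0, 1)
  flat <- power_vs_n(null, n_range = 2:10)
  expect_true(all(abs(flat$power - null$alpha_star) < 1e-12))
})

test_that("dispersion-percentile curves are ordered and consistent", {
  pilot <- gen_normal_omic(m = 2000, n = 10, p1 = 0.3, delta = 1.5,
                           sigma = 1, seed = 17)
  opp <- estimate_power_params(pilot, d0 = 0.8)
  nr <- 2:40
  fam <- power_vs_dispersion(opp, percentiles = c(60, 75, 90),
                             n_range = nr)
  p60 <- fam$power[fam$percentile == 60]
  p75 <- fam$power[fam$percentile == 75]
  p90 <- fam$power[fam$percentile == 90]
  expect_true(all(p60 >= p75 - 1e-12))
  expect_true(all(p75 >= p90 - 1e-12))
  # the k = 75 curve reproduces the main design's power at its optimum
  res <- solve_equal(list(opp), design_constraints(n_max = 40))
  opt <- res$summary$optSampleSize
  expect_equal(p75[match(opt, nr)], res$summary$power, tolerance = 1e-12)
  expect_error(power_vs_dispersion(opp, percentiles = c(2)), "percentile")
})

test_that("degenerate dispersion distributions give identical curves", {
  st <- data.frame(feature = paste0("f", 1:30), delta = rep(2, 30),
                   psd = rep(0.7, 30), d = rep(2 / 0.7, 30))
  opp <- manual_power_params("deg", normal_params(2, 0.7), m = 30, p1 = 0.5)
  opp$stats <- st
  opp$d0 <- 0.8
  fam <- power_vs_dispersion(opp, percentiles = c(60, 75, 90),
                             n_range = 2:10)
  byk <- split(fam$power, fam$percentile)
  expect_equal(byk[["60"]], byk[["75"]])
  expect_equal(byk[["75"]], byk[["90"]])
})

test_that("the d-grid reproduces the main optimum at d0 and is monotone", {
  pilot <- gen_normal_omic(m = 3000, n = 10, p1 = 0.3, delta = 1.6,
                           sigma = 1, seed = 23)
  opp <- estimate_power_params(pilot, d0 = 0.8)
  main <- solve_equal(list(opp))
  grid <- post_d_grid(list(opp), grid_size = 12)
  expect_equal(grid$optSampleSize[1], main$summary$optSampleSize)
  # d_max equals the brute-force minimum of per-omic 90th percentiles
  expect_equal(attr(grid, "d_max"),
               unname(quantile(opp$stats$d, 0.9, type = 7)))
  # coarse monotonicity: required n at the largest d is no larger than at d0
  expect_lte(grid$optSampleSize[nrow(grid)], grid$optSampleSize[1])
  # n_target readout: smallest grid d whose optimum fits the budget
  nt <- grid$optSampleSize[1]
  g2 <- post_d_grid(list(opp), n_target = nt, grid_size = 12)
  expect_equal(attr(g2, "d_for_n_target"), g2$d[1])
})

test_that("d-grid rejects a d0 at or above d_max", {
  pilot <- gen_normal_omic(m = 500, n = 10, p1 = 0.3, delta = 1.6,
                           sigma = 1, seed = 29)
  st <- compute_feature_stats(pilot)
  d_hi <- unname(quantile(st$d, 0.95, type = 7))
  opp <- estimate_power_params(pilot, d0 = d_hi)
  expect_error(post_d_grid(list(opp)), "smaller d0")
})

test_that("two-group multigroup design equals the two-group pipeline", {
  pilot <- gen_normal_omic(m = 800, n = 8, p1 = 0.3, delta = 1.5, sigma = 1,
                           seed = 31)
  direct <- solve_equal(list(estimate_power_params(pilot, d0 = 0.8)))
  mg <- multigroup_design(list(pilot), d0 = 0.8)
  expect_equal(mg$global_opt, direct$summary$optSampleSize)
  expect_identical(nrow(mg$summary), 1L)
})

test_that("three-group design takes the maximum over pairwise optima", {
  set.seed(37)
  m <- 600; n <- 8
  # group C far from A and B; pair (A, B) has the weakest effect
  mk <- function(shift) matrix(rnorm(m * n, shift, 1), m, n)
  de <- 1:180
  matA <- mk(0); matB <- mk(0); matC <- mk(0)
  matB[de, ] <- matB[de, ] + 0.9
  matC[de, ] <- matC[de, ] + 2.5
  mat <- cbind(matA, matB, matC)
  rownames(mat) <- paste0("f", 1:m)
  pilot <- omic_pilot("tri", mat, rep(c("A", "B", "C"), each = n),
                      data_type = "normal", p1 = 0.3)
  mg <- multigroup_design(list(pilot), d0 = 0.8)
  expect_identical(nrow(mg$summary), 3L)
  per <- vapply(mg$per_comparison, function(r) r$summary$optSampleSize[1],
                integer(1))
  expect_equal(mg$global_opt, max(per))
  expect_equal(unname(which.max(per)), 1L)  # A_vs_B needs the most samples
  # explicit comparison list restricts the output
  mg2 <- multigroup_design(list(pilot), comparisons = list(c("A", "C")),
                           d0 = 0.8)
  expect_identical(mg2$summary$comparison, "A_vs_C")
  expect_error(multigroup_design(list(pilot),
                                 comparisons = list(c("A", "Z"))),
               "unknown group")
})

test_that("no-pilot defaults match the recommended values and solve", {
  def <- defaults_without_pilot()
  expect_equal(def$normal$sigma, 1)
  expect_equal(def$count$omega, 2)
  expect_equal(def$count$mu, 30)
  opps <- list(manual_power_params("norm", def$normal, m = 1000, p1 = 0.2),
               manual_power_params("cnt", def$count, m = 2000, p1 = 0.2))
  res <- solve_equal(opps, design_constraints(n_max = 100))
  expect_true(res$feasible)
  expect_true(is.finite(res$summary$optSampleSize[1]))
})

test_that("curve tables are pure functions of the stored parameters", {
  o <- mk_omic("a", 1.3, 1.1)
  expect_identical(power_vs_n(o, 2:25), power_vs_n(o, 2:25))
})
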