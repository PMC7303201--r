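toy_pilot <- function() {
  # 2 features x (3 + 3) samples with hand-computable statistics
  mat <- rbind(f1 = c(1, 2, 3, 5, 6, 7),
               f2 = c(4, 4, 4, 4, 4, 4))
  omic_pilot("toy", mat, rep(c("A", "B"), each = 3), data_type = "normal",
             p1 = 0.5)
}

test_that("feature statistics match hand computation on a toy pilot", {
  st <- compute_feature_stats(toy_pilot())
  expect_equal(st$meanA, c(2, 4))
  expect_equal(st$meanB, c(6, 4))
  expect_equal(st$delta, c(4, 0))
  # pooled SD of f1: both group variances are 1
  expect_equal(st$psd, c(1, 0))
  expect_equal(st$d, c(4, 0))   # identical-value feature has d = 0, not NaN
})

test_that("binary statistics use Cohen's h, with h = pi at full separation", {
  mat <- rbind(f1 = c(1, 1, 1, 0, 0, 0),
               f2 = c(1, 0, 1, 1, 0, 1))
  p <- omic_pilot("bin", mat, rep(c("A", "B"), each = 3),
                  data_type = "binary")
  st <- compute_feature_stats(p)
  expect_equal(st$d[1], pi)
  expect_equal(st$d[2], 0)
})

test_that("depth normalization: hand-computed w and equalized column sums", {
  # group A depths 1e6, 1e6; group B depths 2e6, 2e6
  mat <- matrix(c(rep(250, 8)), nrow = 2)
  mat[, 3:4] <- 500
  mat <- mat * 2000                      # depths 1e6,1e6,2e6,2e6
  rownames(mat) <- c("f1", "f2")
  colnames(mat) <- paste0("s", 1:4)
  p <- omic_pilot("cnt", mat, c("A", "A", "B", "B"), data_type = "count")
  nc <- normalize_counts(p)
  expect_equal(nc$w, exp(mean(log(c(2e6, 2e6)))) / exp(mean(log(c(1e6, 1e6)))))
  expect_equal(nc$w, 2)
  # every normalized sample has depth equal to the median raw depth
  expect_equal(unname(colSums(nc$matrix)), rep(median(colSums(mat)), 4))
})

test_that("equal depths leave counts untouched with w = 1", {
  set.seed(1)
  vals <- rpois(20, 50)
  mat <- sapply(1:10, function(i) sample(vals))  # equal column sums
  rownames(mat) <- paste0("f", 1:20)
  p <- omic_pilot("cnt", mat, rep(c("A", "B"), each = 5),
                  data_type = "count")
  nc <- normalize_counts(p)
  expect_equal(nc$w, 1)
  expect_equal(nc$matrix, p$matrix)
})

test_that("per-sample depth distortion is removed up to a global factor", {
  set.seed(2)
  base <- gen_count_omic(m = 300, n = 4, p1 = 0.2, mu = 40, seed = 9)
  fac <- c(1, 2, 0.5, 1.5, 1, 3, 0.8, 1.2)
  distorted <- base
  distorted$matrix <- sweep(base$matrix, 2, fac, "*")
  n1 <- normalize_counts(base)
  n2 <- normalize_counts(distorted)
  ratio <- n2$matrix / n1$matrix
  ratio <- ratio[is.finite(ratio)]
  expect_lt(diff(range(ratio)), 1e-8)
})

test_that("zero-depth samples are rejected by name", {
  mat <- matrix(c(0, 0, 5, 5, 5, 5, 4, 6), nrow = 2)
  rownames(mat) <- c("f1", "f2")
  colnames(mat) <- c("bad", "s2", "s3", "s4")
  p <- omic_pilot("cnt", mat, c("A", "A", "B", "B"), data_type = "count")
  expect_error(suppressWarnings(compute_feature_stats(p)), "bad")
})

test_that("pseudo-DE selection is a strict threshold with an actionable error", {
  st <- data.frame(feature = c("a", "b", "c"), d = c(0.8, 0.81, 2))
  expect_identical(select_pseudo_de(st, 0.8), c("b", "c"))
  expect_identical(select_pseudo_de(st, 0), c("a", "b", "c"))
  expect_error(select_pseudo_de(st, 5), "lower")
  # all-null data yields (near) nothing above a standard threshold
  null_pilot <- gen_normal_omic(m = 2000, n = 10, p1 = 0, delta = 0,
                                sigma = 1, seed = 3)
  st0 <- compute_feature_stats(null_pilot)
  expect_lt(sum(st0$d > 0.8) / nrow(st0), 0.12)
})

test_that("percentile estimation equals the brute-force oracle", {
  set.seed(11)
  psd <- rlnorm(100, 0, 0.4)
  delta <- rnorm(100, 1.5, 0.5)
  st <- data.frame(feature = paste0("f", 1:100), delta = delta, psd = psd,
                   d = abs(delta) / psd)
  for (k in c(60, 75, 90)) {
    est <- estimate_normal_params(st, st$feature, k = k)
    orc <- oracle_normal_estimate(psd, delta, k)
    expect_equal(est$sigma, orc$sigma)
    expect_equal(est$delta, orc$delta)
  }
})

test_that("degenerate pseudo-DE distributions return their single value", {
  st <- data.frame(feature = paste0("f", 1:20), delta = rep(1, 20),
                   psd = rep(0.5, 20), d = rep(2, 20))
  for (k in c(60, 75, 90)) {
    est <- estimate_normal_params(st, st$feature, k = k)
    expect_equal(est$sigma, 0.5)
    expect_equal(est$delta, 1)
  }
})

# The dispersion summary stacks the per-condition variances of all
# pseudo-DE features and takes their P_k: because differentially expressed
# features have one condition at an omega-fold higher mean (hence roughly
# omega^2-fold higher NB variance), the summary is conservative by
# construction whenever fold changes are present. The tests below pin the
# unbiased Poisson limit, the bounded-conservatism envelope, and the fold
# change / depth-ratio recovery on a homogeneous composition-neutral pilot.
test_that("count parameter estimation: Poisson-like data gives phi near 0", {
  p <- gen_count_omic(m = 3000, n = 10, p1 = 0.2, mu = 40, phi = 0,
                      omega = 2, sdlog = 0.05, seed = 21)
  opp <- estimate_power_params(p, d0 = 1.5)
  expect_lt(opp$params$phi, 0.05)
  expect_gt(opp$params$omega, 1.5)
  expect_lt(opp$params$omega, 2.6)
})

test_that("count dispersion is recovered up to its documented conservatism", {
  p <- gen_count_omic(m = 5000, n = 10, p1 = 0.2, mu = 40, phi = 0.4,
                      omega = 2, sdlog = 0.05, seed = 31)
  opp <- estimate_power_params(p, d0 = 1)
  # never anti-conservative, and bounded by the omega^2 variance envelope
  expect_gt(opp$params$phi, 0.4 * 0.7)
  expect_lt(opp$params$phi, 0.4 * 2^2 * 1.4)
  expect_gt(opp$params$mu, 0)
  expect_gt(opp$params$omega, 1.3)
  # composition-neutral generator with equal depth factors: w recovered as 1
  expect_equal(opp$params$w, 1, tolerance = 0.05)
})

test_that("count estimation matches a brute-force oracle on a fixed table", {
  st <- data.frame(feature = paste0("f", 1:10),
                   meanA = c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100),
                   meanB = c(25, 35, 80, 90, 120, 130, 150, 170, 200, 210),
                   varA = seq(20, 200, by = 20),
                   varB = seq(30, 300, by = 30),
                   psd = sqrt(seq(25, 250, by = 25)),
                   d = rep(2, 10))
  st$delta <- st$meanB - st$meanA
  st$fold_change <- st$meanB / st$meanA
  attr(st, "w") <- 1.3
  k <- 75
  est <- estimate_count_params(st, st$feature, k = k)
  q <- function(v, p) unname(quantile(v, p / 100, type = 7))
  v <- c(st$varA, st$varB)
  sigma2 <- q(v, k)
  lo <- q(v, k - 5); hi <- q(v, k + 5)
  win <- (st$varA >= lo & st$varA <= hi) | (st$varB >= lo & st$varB <= hi)
  mu <- q(st$meanA[win], 100 - k)
  expect_equal(est$mu, mu)
  expect_equal(est$phi, max(0, (sigma2 - mu) / mu^2))
  flo <- q(st$psd, k - 5); fhi <- q(st$psd, k + 5)
  fwin <- st$psd >= flo & st$psd <= fhi
  fc <- pmax(st$fold_change, 1 / st$fold_change)
  expect_equal(est$omega, q(fc[fwin], 100 - k))
  expect_equal(est$w, 1.3)
})

test_that("binary estimation picks the feature at the P_(100-k) of h", {
  set.seed(5)
  pA <- runif(50, 0.05, 0.45); pB <- runif(50, 0.5, 0.95)
  st <- data.frame(feature = paste0("f", 1:50), meanA = pA, meanB = pB,
                   d = cohens_h(pA, pB))
  est <- estimate_binary_params(st, st$feature, k = 75)
  target <- unname(quantile(st$d, 0.25, type = 7))
  pick <- which.min(abs(st$d - target))
  expect_equal(est$pA, pA[pick])
  expect_equal(est$pB, pB[pick])
  # no variability in h: every k returns the same pair
  st2 <- data.frame(feature = paste0("g", 1:5), meanA = rep(0.2, 5),
                    meanB = rep(0.7, 5), d = cohens_h(0.2, 0.7))
  for (k in c(60, 75, 90)) {
    e <- estimate_binary_params(st2, st2$feature, k = k)
    expect_equal(c(e$pA, e$pB), c(0.2, 0.7))
  }
})

test_that("scaling a normal pilot rescales delta/sigma but not d or the design", {
  p1 <- gen_normal_omic(m = 800, n = 8, p1 = 0.25, delta = 1.5, sigma = 1,
                        seed = 13)
  p2 <- p1
  p2$matrix <- p1$matrix * 7
  o1 <- estimate_power_params(p1, d0 = 0.8)
  o2 <- estimate_power_params(p2, d0 = 0.8)
  expect_equal(o2$params$delta, 7 * o1$params$delta)
  expect_equal(o2$params$sigma, 7 * o1$params$sigma)
  expect_equal(o2$alpha_star, o1$alpha_star)
  expect_equal(cohens_d(o2$params$delta, o2$params$sigma),
               cohens_d(o1$params$delta, o1$params$sigma))
  r1 <- solve_equal(list(o1))
  r2 <- solve_equal(list(o2))
  expect_identical(r1$summary$optSampleSize, r2$summary$optSampleSize)
})

test_that("pilot validation rejects malformed inputs", {
  mat <- matrix(c(1, NA, 3, 4), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(omic_pilot("x", mat, c("A", "B"), "normal"), "missing")
  m2 <- matrix(1:8, 2)
  expect_error(omic_pilot("x", m2, c("A", "A", "B", "B"), "binary"), "0/1")
  expect_error(omic_pilot("x", -m2, c("A", "A", "B", "B"), "count"),
               "non-negative")
  expect_error(omic_pilot("x", m2, c("A", "B", "B", "B"), "normal"),
               "two replicates")
  p <- omic_pilot("x", matrix(rnorm(60), 10,
                              dimnames = list(paste0("f", 1:10), NULL)),
                  c("A", "A", "B", "B", "C", "C"), "normal")
  expect_error(compute_feature_stats(p), "two groups")
})
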