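test_that("demean centres exactly, stores the mean, and is idempotent", {
  y <- demean(c(1.0, 1.2, 1.1))
  expect_equal(as.numeric(y), c(-0.1, 0.1, 0.0))
  expect_equal(attr(y, "mean"), 1.1)
  set.seed(4); z <- rnorm(50)
  zc <- demean(z)
  expect_lt(abs(mean(zc)), 1e-12)
  expect_equal(as.numeric(demean(as.numeric(zc))), as.numeric(zc))
  expect_error(demean(c(1, 2)), "length")
})

test_that("biased ACF matches direct summation and its conventions", {
  set.seed(8); y <- rnorm(200)
  cg <- correlogram(y, max_lag = 10)
  expect_equal(cg$acf[1], 1)
  expect_true(all(abs(cg$acf) <= 1 + 1e-12))
  for (k in c(1, 3, 7)) expect_equal(cg$acf[k + 1], oracle_acf(y, k))
  # alternating series: biased lag-1 autocorrelation is -(n-1)/n
  alt <- rep(c(1, -1), 50)
  expect_equal(correlogram(alt, 2)$acf[2], -0.99)
  expect_error(correlogram(rep(2, 30), 5), "constant")
  # agreement with the reference implementation
  ref <- as.numeric(stats::acf(y, lag.max = 10, plot = FALSE,
                               demean = TRUE)$acf)
  expect_equal(cg$acf, ref, tolerance = 1e-12)
})

test_that("PACF follows Durbin-Levinson and the AR cutoff property", {
  set.seed(9); y <- rnorm(300)
  cg <- correlogram(y, max_lag = 12)
  expect_equal(cg$pacf[1], cg$acf[2])
  ref <- as.numeric(stats::pacf(y, lag.max = 12, plot = FALSE)$acf)
  expect_equal(cg$pacf, ref, tolerance = 1e-10)
  sim <- simulate_ar2_series(0.5, 0.2, n = 100000, seed = 14)
  cg2 <- correlogram(sim, max_lag = 20)
  expect_lt(abs(cg2$pacf[2] - 0.2), 0.01)
  expect_gte(mean(abs(cg2$pacf[3:20]) < cg2$bound), 0.9)
})

test_that("conditional least squares recovers known coefficients", {
  wn <- simulate_ar2_series(0, 0, n = 100000, noise_sd = 1, seed = 15)
  f0 <- gait_ar(wn)
  expect_true(all(abs(coef(f0)) < 0.02))
  y <- simulate_ar2_series(0.5, 0.2, n = 100000, noise_sd = 1, seed = 16)
  f <- gait_ar(y)
  expect_lt(max(abs(unname(coef(f)) - c(0.5, 0.2))), 0.01)
  expect_equal(f$sigma2, 1, tolerance = 0.02)
  expect_error(gait_ar(rnorm(5)), "too short")
  expect_error(gait_ar(rep(1, 100)), "constant")
})

test_that("CLS and Yule-Walker match the reference fitters", {
  y <- simulate_ar2_series(0.4, -0.3, n = 3000, seed = 18)
  f <- gait_ar(y)
  ref <- stats::ar.ols(y, aic = FALSE, order.max = 2, demean = TRUE,
                       intercept = FALSE)
  expect_equal(unname(coef(f)), as.numeric(ref$ar), tolerance = 1e-10)
  fyw <- gait_ar(y, method = "yw")
  refyw <- stats::ar.yw(y, aic = FALSE, order.max = 2)
  expect_equal(unname(coef(fyw)), as.numeric(refyw$ar), tolerance = 1e-10)
})

test_that("fitted values plus residuals reconstruct the series for t > p", {
  y <- simulate_ar2_series(0.6, -0.2, n = 500, seed = 20)
  f <- gait_ar(y)
  expect_equal(fitted(f) + residuals(f), y[-(1:2)], tolerance = 1e-12)
  expect_identical(length(residuals(f)), f$n - f$order)
  expect_lt(abs(mean(residuals(f))), 3 * sqrt(f$sigma2 / f$n))
})

test_that("root-coefficient duality holds for fits", {
  for (seed in 1:5) {
    set.seed(seed)
    repeat {
      p1 <- runif(1, -2, 2); p2 <- runif(1, -1, 1)
      if (is_stationary(p1, p2)) break
    }
    y <- simulate_ar2_series(p1, p2, n = 400, seed = seed + 100)
    f <- gait_ar(y)
    m <- f$roots
    expect_equal(Re(m[1] + m[2]), unname(coef(f)[1]), tolerance = 1e-9)
    expect_equal(Re(-m[1] * m[2]), unname(coef(f)[2]), tolerance = 1e-9)
  }
})

test_that("characteristic roots satisfy the characteristic equation", {
  expect_equal(characteristic_roots(0, 0)$roots, c(0 + 0i, 0 + 0i))
  cr <- characteristic_roots(0, -0.5)
  expect_equal(cr$moduli, rep(sqrt(0.5), 2))
  expect_true(all(abs(Im(cr$roots)) > 0))
  cr2 <- characteristic_roots(1.5, -0.56)
  expect_equal(sort(Re(cr2$roots)), c(0.7, 0.8), tolerance = 1e-12)
  expect_equal(Re(cr2$roots), Re(polyroot(c(0.56, -1.5, 1)))[order(-Mod(polyroot(c(0.56, -1.5, 1))))],
               tolerance = 1e-9)
})

test_that("order selection implements the PACF threshold rule", {
  # rule check against an independently computed PACF, across processes:
  # recommended order = largest lag whose |pacf| exceeds 1.96/sqrt(n)
  cases <- list(c(0.5, 0.2), c(0, 0), c(0.6, 0))
  for (i in seq_along(cases)) {
    y <- simulate_ar2_series(cases[[i]][1], cases[[i]][2], 100000,
                             seed = 21 + i)
    so <- select_order(y, max_order = 10)
    ref <- abs(as.numeric(stats::pacf(y, lag.max = 10, plot = FALSE)$acf))
    exceed <- which(ref > 1.96 / sqrt(length(y)))
    expect_identical(as.integer(so$order),
                     if (length(exceed)) max(exceed) else 0L)
  }
  # the identification target: a gait-scale AR(2) fluctuation series shows a
  # prominent PACF at lag 2
  y2 <- simulate_ar2_series(0.66, -0.55, 5000, noise_sd = 0.02, seed = 25)
  so2 <- select_order(y2, max_order = 8)
  expect_gte(so2$order, 2L)
  expect_gt(abs(so2$pacf[2]), so2$bound)
  expect_error(select_order(rnorm(20), max_order = 10), "n/4")
})

test_that("Anderson-Darling decision separates normal from skewed residuals", {
  set.seed(26)
  expect_false(ad_normality(rnorm(5000))$reject)
  expect_true(ad_normality(rexp(5000))$reject)
  expect_error(ad_normality(rep(1, 50)), "zero variance")
  expect_error(ad_normality(rnorm(5)), "at least 8")
})

test_that("raw A2 statistic matches the reference implementation", {
  skip_if_not_installed("nortest")
  set.seed(27); x <- rnorm(80)
  expect_equal(ad_normality(x)$statistic,
               unname(nortest::ad.test(x)$statistic), tolerance = 1e-12)
})

test_that("fit object methods are coherent", {
  y <- simulate_ar2_series(0.66, -0.55, n = 300, noise_sd = 0.02, mean = 1.08,
                           seed = 30)
  f <- gait_ar(y)
  expect_s3_class(f, "gait_ar")
  expect_identical(names(coef(f)), c("phi1", "phi2"))
  expect_true(f$stationary)
  expect_equal(f$distance, centroid_distance(coef(f)[[1]], coef(f)[[2]]))
  expect_equal(f$delta, f$mean * (1 - sum(coef(f))), tolerance = 1e-12)
  s <- summary(f)
  expect_s3_class(s, "summary.gait_ar")
  expect_output(print(s), "Anderson-Darling")
  fc <- predict(f, n.ahead = 5)
  expect_length(fc, 5)
  # long-horizon forecast converges to the series mean
  expect_equal(predict(f, n.ahead = 500)[500], f$mean, tolerance = 1e-6)
  sim <- simulate(f, nsim = 2, seed = 1, n = 50)
  expect_identical(dim(sim), c(50L, 2L))
  expect_identical(simulate(f, seed = 2, n = 20), simulate(f, seed = 2, n = 20))
})
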