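test_that("tricube kernel has the right shape", {
  expect_identical(tricube(0), 1)
  expect_identical(tricube(1), 0)
  expect_equal(tricube(0.5), 0.669921875)   # (1 - 1/8)^3 = (7/8)^3
  u <- seq(0, 2, by = 0.001)
  w <- tricube(u)
  expect_true(all(diff(w) <= 1e-12))        # nonincreasing
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all(w[u >= 1] == 0))
  expect_error(tricube(-0.1), "nonnegative")
})

test_that("neighborhood selects span-nearest points with record-order ties", {
  nb <- loess_neighborhood(matrix(1:10), target = 1, span = 0.3)
  expect_identical(nb$indices, 1:3)
  expect_equal(nb$bandwidth, 2)
  nb_full <- loess_neighborhood(matrix(1:10), target = 1, span = 1)
  expect_identical(sort(nb_full$indices), 1:10)
  expect_equal(nb_full$bandwidth, 9)
  # ceiling rule at scale: 10% of 10,000 points is a 1,000-point window
  set.seed(1)
  big <- matrix(runif(10000))
  expect_equal(loess_neighborhood(big, 0.5, 0.1)$k, 1000)
  # equidistant boundary tie goes to the earlier record
  co <- matrix(c(0, 0.5, 1, -1, 2))
  nb_tie <- loess_neighborhood(co, target = 0, span = 0.6)
  expect_identical(nb_tie$indices, c(1L, 2L, 3L))
  expect_equal(nb_tie$bandwidth, 1)
  expect_error(loess_neighborhood(matrix(numeric(), 0, 1), 0, 0.5))
})

test_that("local linear fit matches a from-scratch weighted solve", {
  # 5 points on a parabola, full-span window
  x <- 0:4
  y <- x^2
  lf <- local_linear_fit(matrix(x), y, target = 2, span = 1)
  d <- abs(x - 2)
  h <- max(d)
  ww <- ifelse(d / h < 1, (1 - (d / h)^3)^3, 0)
  D <- cbind(1, x - 2)
  expect_equal(lf$fitted,
               drop(solve(crossprod(D, D * ww), crossprod(D, ww * y)))[1],
               tolerance = 1e-12)
  # the hat row reproduces the fit as a linear functional
  expect_equal(sum(lf$hat_row * y), lf$fitted, tolerance = 1e-12)
  # constants and linear responses are reproduced exactly
  expect_equal(local_linear_fit(matrix(x), rep(7, 5), 1.3, 0.8)$fitted, 7)
  expect_equal(local_linear_fit(matrix(x), 2 + 3 * x, 1.3, 0.6)$fitted,
               2 + 3 * 1.3)
  # coincident neighbours fall back to the weighted mean with a warning
  expect_warning(
    cf <- local_linear_fit(matrix(rep(1, 4)), c(1, 2, 3, 4), 1, 1),
    "rank-deficient")
  expect_equal(cf$fitted, 2.5)
})

test_that("loess smooth equals the independent WLS oracle", {
  set.seed(42)
  for (case in list(list(n = 50, d = 1, span = 0.3),
                    list(n = 120, d = 2, span = 0.2),
                    list(n = 200, d = 2, span = 0.65))) {
    co <- matrix(runif(case$n * case$d), ncol = case$d)
    y <- sin(4 * co[, 1]) + rnorm(case$n, 0, 0.3)
    w <- runif(case$n, 0.2, 3)
    f <- loess_smooth(co, y, span = case$span, weights = w)
    expect_lt(max(abs(f$fitted - loess_oracle(co, y, case$span, w))), 1e-10)
  }
})

test_that("loess reproduces linear responses at every span", {
  set.seed(7)
  n <- 80
  co <- cbind(runif(n), runif(n))
  y <- 1.5 - 2 * co[, 1] + 0.7 * co[, 2]
  w <- runif(n, 0.5, 2)
  for (s in c(0.1, 0.3, 0.5, 0.8, 1)) {
    f <- loess_smooth(co, y, span = s, weights = w)
    expect_lt(max(abs(f$fitted - y)), 1e-8)
  }
})

test_that("smoother trace decreases with span", {
  set.seed(3)
  n <- 150
  co <- cbind(runif(n), runif(n))
  y <- rnorm(n)
  spans <- c(0.1, 0.2, 0.4, 0.6, 0.8, 1)
  tr <- vapply(spans, function(s) loess_smooth(co, y, span = s)$trace,
               numeric(1))
  expect_true(all(diff(tr) <= 1e-6))
  expect_true(all(tr >= 1 - 1e-8))
  expect_true(all(tr <= n))
})

test_that("prediction at new points interpolates the smooth", {
  set.seed(5)
  n <- 60
  x <- sort(runif(n))
  y <- cos(3 * x) + rnorm(n, 0, 0.1)
  f <- loess_smooth(x, y, span = 0.5)
  expect_equal(predict(f, matrix(x[10])), f$fitted[10], tolerance = 1e-12)
})
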