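test_that("parametric logistic fit matches closed forms", {
  # intercept-only: logit of the case fraction
  y <- rep(c(1, 0), c(30, 70))
  f <- fit_parametric_logistic(y)
  expect_equal(f$intercept, qlogis(0.3), tolerance = 1e-6)
  # balanced intercept-only deviance is 2 n ln 2
  f50 <- fit_parametric_logistic(rep(c(1, 0), each = 50))
  expect_equal(f50$deviance, 2 * 100 * log(2), tolerance = 1e-4)
  expect_equal(f50$deviance, 138.6294, tolerance = 1e-4)
  # two-group covariate recovers the contingency-table log odds ratio
  z <- rep(c(1, 0), each = 100)
  y2 <- c(rep(c(1, 0), c(20, 80)), rep(c(1, 0), c(10, 90)))
  f2 <- fit_parametric_logistic(y2, cbind(exposed = z))
  expect_equal(unname(f2$gamma["exposed"]), log((20 * 90) / (80 * 10)),
               tolerance = 1e-6)
})

test_that("gam_aic is deviance plus twice the effective df", {
  expect_equal(gam_aic(100, 3), 106)
  expect_equal(gam_aic(0, 0), 0)
  expect_gt(gam_aic(50, 10), gam_aic(50, 6))
})

test_that("the GAM nests the reduced model in deviance", {
  set.seed(11)
  for (i in 1:100) {
    n <- 60
    d <- ed_dataset(data.frame(x = runif(n), y = runif(n),
                               day = sample(1:10, n, TRUE),
                               outcome = rbinom(n, 1, 0.4),
                               age = runif(n, 0, 80)))
    f <- edgam(d, "space", span = 0.8)
    expect_lte(f$deviance, f$reduced$deviance + 1e-6)
    expect_gte(f$deviance, 0)
    expect_gte(f$edf, 2)
  }
})

test_that("the smooth term is centred and the fit is well formed", {
  d <- generate_dataset(flat_config(n = 600, seed = 21))
  f <- edgam(d, "space", span = 0.6)
  w <- f$working$weights
  expect_lt(abs(sum(w * f$smooth) / sum(w)), 1e-8)
  expect_true(f$converged)
  expect_equal(f$aic, f$deviance + 2 * f$edf)
  expect_equal(unname(logLik(f)), -f$deviance / 2, ignore_attr = TRUE)
  expect_equal(attr(logLik(f), "df"), f$edf)
  # deviance residuals square-sum to the deviance
  expect_equal(sum(residuals(f)^2), f$deviance, tolerance = 1e-8)
})

test_that("a flat-risk simulation yields a nearly flat smooth", {
  d <- generate_dataset(flat_config(n = 2000, seed = 31))
  f <- edgam(d, "space", span = 0.9)
  # bulk of the smooth is near zero; edge records may wobble more
  expect_lt(unname(quantile(abs(f$smooth), 0.95)), 0.3)
  expect_lt(max(abs(f$smooth)), 0.8)
  expect_lt(f$reduced$deviance - f$deviance, 30)  # within chi-square noise
})

test_that("an exactly linear logit surface is recovered", {
  set.seed(41)
  n <- 4000
  x <- runif(n, 0, 10)
  y <- runif(n, 0, 10)
  eta <- -0.5 + 0.25 * x - 0.2 * y
  d <- ed_dataset(data.frame(x = x, y = y, day = sample(1:30, n, TRUE),
                             outcome = rbinom(n, 1, plogis(eta)),
                             age = runif(n, 0, 80)))
  eta_sorted <- -0.5 + 0.25 * d$x - 0.2 * d$y
  f <- edgam(d, "space", span = 0.9)
  expect_gt(cor(f$eta, eta_sorted), 0.95)
})

test_that("degenerate single-class windows are refused", {
  d <- ed_dataset(data.frame(x = runif(20), y = runif(20), day = 1:20,
                             outcome = rep(1L, 20), age = runif(20)))
  expect_error(edgam(d, "space", 0.9), "degenerate window")
})

test_that("prediction is consistent in-sample and additive in covariates", {
  d <- generate_dataset(flat_config(n = 500, seed = 51))
  f <- edgam(d, "space", span = 0.7)
  # at a data point, prediction at that record's covariates matches eta
  i <- 17
  p <- predict(f, cbind(d$x[i], d$y[i]), z_ref = d$age[i])
  expect_equal(p, unname(f$eta[i]), tolerance = 1e-10)
  # shifting z_ref by delta shifts all predictions by gamma * delta exactly
  pts <- cbind(runif(5, 2, 8), runif(5, 2, 8))
  p0 <- predict(f, pts, z_ref = 40)
  p1 <- predict(f, pts, z_ref = 45)
  expect_equal(p1 - p0, rep(unname(f$gamma) * 5, 5), tolerance = 1e-10)
})

test_that("grid prediction localizes a planted hotspot", {
  cfg <- recovery_config(seed = 3)
  d <- generate_dataset(cfg)
  f <- edgam(d, "space", span = 0.08)
  g <- recovery_grid(d)
  or <- odds_ratio_map(f, grid = g)
  inside <- true_or_surface(cfg, g) > 1 & g$active
  expect_true(inside[which.max(or)])
})

test_that("span selection minimizes AIC with smoother-tie preference", {
  d <- generate_dataset(flat_config(n = 400, seed = 61))
  expect_equal(select_span(d, "space", candidate_spans = 0.5)$span, 0.5)
  sel <- select_span(d, "space", candidate_spans = c(0.3, 0.6, 0.9))
  expect_equal(sel$span, sel$aic_table$span[which.min(sel$aic_table$aic)])
  expect_equal(nrow(sel$aic_table), 3)
})

test_that("flat truth selects larger spans than a sharp hotspot", {
  spans <- c(0.05, 0.1, 0.2, 0.4, 0.7, 0.95)
  flat_sel <- numeric(3)
  hot_sel <- numeric(3)
  for (i in 1:3) {
    dflat <- generate_dataset(flat_config(n = 3000, seed = 70 + i))
    cfg_hot <- recovery_config(seed = 70 + i, n = 3000)
    dhot <- generate_dataset(cfg_hot)
    flat_sel[i] <- select_span(dflat, "space", spans)$span
    hot_sel[i] <- select_span(dhot, "space", spans)$span
  }
  # flat truth is best served by heavy smoothing
  expect_gte(min(flat_sel), 0.4)
  # the planted hotspot demands finer resolution than flat truth
  expect_true(mean(hot_sel) < mean(flat_sel))
})

test_that("flat-risk OR surfaces stay near 1 across replicates", {
  hits <- 0L
  total <- 0L
  for (s in 1:20) {
    d <- generate_dataset(flat_config(n = 2000, seed = 100 + s))
    # flat truth is smoothed maximally (the full-data window)
    f <- edgam(d, "space", span = 1)
    g <- apply_mask(make_grid(d, 15, 15), data = d, max_mask_distance = 0.5,
                    min_points = 10)
    or <- odds_ratio_map(f, grid = g)
    or <- or[g$active]
    hits <- hits + sum(or >= 0.8 & or <= 1.25)
    total <- total + length(or)
  }
  expect_gte(hits / total, 0.95)
})
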