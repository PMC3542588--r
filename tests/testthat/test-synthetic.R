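test_that("generated datasets have the configured size and ordering", {
  d <- generate_dataset(synthetic_config(n_records = 500, seed = 5))
  expect_equal(nrow(d), 500)
  expect_true(!is.unsorted(d$day))
  expect_true(all(d$outcome %in% 0:1))
  expect_true(all(d$age >= 0 & d$age <= 106))
  expect_s3_class(d, "ed_dataset")
})

test_that("generation is reproducible from config and seed", {
  cfg <- synthetic_config(n_records = 300, seed = 9,
                          hotspots = list(hotspot(c(5, 5), 1, log(2))))
  expect_identical(as.data.frame(generate_dataset(cfg)),
                   as.data.frame(generate_dataset(cfg)))
  d1 <- generate_dataset(cfg, seed = 10)
  expect_false(identical(as.data.frame(d1),
                         as.data.frame(generate_dataset(cfg))))
})

test_that("the case fraction matches the configured baseline", {
  cfg <- synthetic_config(n_records = 20000, seed = 13,
                          baseline_case_odds = 0.25)
  d <- generate_dataset(cfg)
  p0 <- 0.25 / 1.25
  se <- sqrt(p0 * (1 - p0) / 20000)
  expect_lt(abs(mean(d$outcome) - p0), 3 * se)
})

test_that("a persistent disc hotspot realizes its contingency odds ratio", {
  cfg <- synthetic_config(n_records = 20000, seed = 17,
                          hotspots = list(hotspot(c(5, 5), 2, log(2))))
  d <- generate_dataset(cfg)
  inside <- (d$x - 5)^2 + (d$y - 5)^2 < 4
  tab <- table(inside, d$outcome)
  or <- (tab["TRUE", "1"] * tab["FALSE", "0"]) /
    (tab["TRUE", "0"] * tab["FALSE", "1"])
  expect_gt(or, 1.8)
  expect_lt(or, 2.2)
})

test_that("stored truth probabilities are re-derivable from the records", {
  cfg <- synthetic_config(n_records = 1000, seed = 19, age_log_or = 0.01,
                          hotspots = list(hotspot(c(6, 6), 1.5, log(3),
                                                  active_days = c(20, 200))))
  d <- generate_dataset(cfg)
  truth <- attr(d, "truth")
  logit <- log(cfg$baseline_case_odds) +
    cfg$age_log_or * (d$age - cfg$age_distribution[["mean"]]) +
    edgam:::hotspot_contribution(cfg, d$x, d$y, d$day)
  expect_lt(max(abs(plogis(logit) - truth$p)), 1e-12)
})

test_that("seasonality and cluster weights are realized", {
  cfg <- synthetic_config(n_records = 40000, seed = 23,
                          seasonal_amplitude = 2, study_days = 365)
  d <- generate_dataset(cfg)
  inten <- edgam:::seasonal_intensity(cfg)
  hi <- which(inten >= quantile(inten, 0.75))
  lo <- which(inten <= quantile(inten, 0.25))
  emp_ratio <- (sum(d$day %in% hi) / length(hi)) /
    (sum(d$day %in% lo) / length(lo))
  th_ratio <- mean(inten[hi]) / mean(inten[lo])
  expect_lt(abs(emp_ratio / th_ratio - 1), 0.1)
  cl <- attr(d, "truth")$cluster
  w <- cfg$population_clusters$weight
  for (j in seq_along(w)) {
    se <- sqrt(w[j] * (1 - w[j]) / nrow(d))
    expect_lt(abs(mean(cl == j) - w[j]), 3 * se)
  }
})

test_that("the true OR surface multiplies overlapping active hotspots", {
  cfg <- synthetic_config(
    n_records = 10, seed = 1,
    hotspots = list(hotspot(c(5, 5), 2, log(2)),
                    hotspot(c(6, 5), 2, log(1.5), active_days = c(1, 10))))
  pts <- data.frame(x = c(5, 5.5, 9.9), y = c(5, 5, 9.9))
  expect_equal(true_or_surface(cfg, pts, day = 1), c(3, 3, 1))
  expect_equal(true_or_surface(cfg, pts, day = 50), c(2, 2, 1))
  flat <- synthetic_config(n_records = 10, seed = 1)
  expect_equal(true_or_surface(flat, pts), c(1, 1, 1))
})

test_that("the Cape-Cod-scale preset matches its documented magnitudes", {
  cfg <- cape_cod_like_config()
  expect_equal(cfg$n_records, 44421L)
  expect_equal(cfg$study_days, 1826L)
  d <- generate_dataset(cape_cod_like_config(n_records = 20000, seed = 3))
  p0 <- 7111 / 44421
  # hotspots nudge the realized fraction slightly above baseline
  expect_lt(abs(mean(d$outcome) - p0), 0.02)
})
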