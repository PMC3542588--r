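# Shared study designs used across tests.

# flat spatial risk: no hotspots, no age effect
flat_config <- function(n = 800, seed = 1, study_days = 60) {
  synthetic_config(n_records = n, study_days = study_days, seed = seed)
}

# the recovery design: a disc hotspot of true OR 2 covering a dense town
# cluster (8% of the population) over a diffuse background; balanced
# case-control baseline for maximum per-record information
recovery_config <- function(seed = 1, n = 5000) {
  synthetic_config(
    n_records = n, study_days = 90, seed = seed,
    population_clusters = data.frame(x = c(4, 7), y = c(4, 7),
                                     weight = c(0.92, 0.08),
                                     spread = c(2.8, 0.8)),
    baseline_case_odds = 0.9,
    hotspots = list(hotspot(c(7, 7), 1.6, log(2))))
}

recovery_spans <- function() c(0.03, 0.05, 0.08)

recovery_grid <- function(d) {
  apply_mask(make_grid(d, 25, 25), data = d, max_mask_distance = 0.5,
             min_points = 10)
}

# uniform stream: exactly `per_day` records on each of `days` days
uniform_dataset <- function(days = 100, per_day = 10, seed = 1) {
  n <- days * per_day
  set.seed(seed)
  ed_dataset(data.frame(x = runif(n), y = runif(n),
                        day = rep(seq_len(days), each = per_day),
                        outcome = rbinom(n, 1, 0.3),
                        age = runif(n, 0, 80)))
}

# the worked-example stream: 10,000 records whose first 1,000 have record
# 300 on day 25 and record 500 (the median) on day 35, then 20 records/day
worked_example_dataset <- function() {
  days <- c(rep(1:25, each = 12),          # records 1..300
            rep(26:35, each = 20),         # records 301..500
            rep(36:60, each = 20),         # records 501..1000
            rep(61:510, each = 20))        # records 1001..10000
  set.seed(99)
  n <- length(days)
  ed_dataset(data.frame(x = runif(n), y = runif(n), day = days,
                        outcome = rbinom(n, 1, 0.3), age = runif(n, 0, 80)))
}

# independently coded weighted-least-squares loess oracle: normal equations
# assembled from scratch at each point
loess_oracle <- function(coords, y, span, w = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(w)) w <- rep(1, n)
  k <- max(ceiling(span * n), ncol(coords) + 1)
  vapply(seq_len(n), function(j) {
    d <- sqrt(rowSums((coords - matrix(coords[j, ], n, ncol(coords),
                                       byrow = TRUE))^2))
    o <- order(d, seq_len(n))
    idx <- o[seq_len(k)]
    h <- d[idx[k]]
    u <- if (h > 0) d[idx] / h else rep(0, k)
    ww <- w[idx] * ifelse(u < 1, (1 - u^3)^3, 0)
    D <- cbind(1, coords[idx, , drop = FALSE] -
                 matrix(coords[j, ], k, ncol(coords), byrow = TRUE))
    drop(solve(crossprod(D, D * ww), crossprod(D, ww * y[idx])))[1]
  }, numeric(1))
}
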