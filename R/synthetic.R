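#' Define a circular risk elevation for the synthetic generator
#'
#' A hard-disc elevation: records inside `radius` of `center`, on an active
#' study day, have `log_or` added to their case log odds. Persistent hotspots
#' span the whole study; transient ones carry a day interval. The hard-disc
#' shape makes an exact inside/outside contingency-table oracle possible; a
#' smooth Gaussian-bump option exists via `hotspot_shape` in
#' [synthetic_config()].
#'
#' @param center length-2 numeric, `(x, y)` centre.
#' @param radius disc radius, coordinate units; > 0.
#' @param log_or added log odds inside the active disc (e.g. `log(2)`).
#' @param active_days length-2 integer day interval; `c(1, Inf)` = persistent.
#' @export
hotspot <- function(center, radius, log_or, active_days = c(1, Inf)) {
  stopifnot(length(center) == 2, radius > 0, length(active_days) == 2,
            active_days[1] >= 1, active_days[1] <= active_days[2])
  structure(list(center = as.numeric(center), radius = radius,
                 log_or = log_or, active_days = active_days),
            class = "ed_hotspot")
}

#' Configuration of a synthetic ED case-control stream
#'
#' Full generative description of a simulated emergency-department dataset:
#' visit days follow a sinusoidal seasonal intensity with a winter peak,
#' locations come from a mixture of population clusters (bivariate normal,
#' truncated to the bounding box), age from a truncated normal, and case
#' status from a Bernoulli draw whose logit combines a baseline, a linear age
#' effect, and any active hotspot elevations.
#'
#' @param n_records number of records to generate.
#' @param study_days study period length in days.
#' @param bbox study bounding box `c(xmin, xmax, ymin, ymax)`.
#' @param population_clusters data.frame with columns `x`, `y`, `weight`,
#'   `spread` describing the control-population location mixture; weights are
#'   normalized to sum to 1.
#' @param seasonal_amplitude winter/summer visit-intensity ratio (1 = no
#'   seasonality; 2 = winter days twice as busy as summer days).
#' @param peak_day day of the year at which visit intensity peaks (default 15,
#'   mid-January when day 1 is January 1).
#' @param seasonal_mode `"all"` (default: the seasonal visit intensity applies
#'   to every record, so the risk surface, not visit behaviour, carries the
#'   signal) or `"controls-only"` (only controls' visit days are seasonal — a
#'   probe of shifting-reference behaviour).
#' @param baseline_case_odds baseline odds of being a case (cases : controls).
#' @param age_distribution named or ordered vector `(mean, sd, min, max)` of
#'   the truncated-normal age distribution, years.
#' @param age_log_or per-year additive effect of `age - mean(age)` on the case
#'   log odds.
#' @param hotspots list of [hotspot()] objects.
#' @param hotspot_shape `"disc"` (default, indicator inside the radius) or
#'   `"gaussian"` (`log_or * exp(-d^2 / (2 radius^2))`, no sharp edge).
#' @param seed integer RNG seed; every draw of [generate_dataset()] flows from
#'   it.
#' @return object of class `ed_synth_config`.
#' @seealso [generate_dataset()], [true_or_surface()], [cape_cod_like_config()]
#' @export
synthetic_config <- function(n_records = 2000,
                             study_days = 365,
                             bbox = c(0, 10, 0, 10),
                             population_clusters = data.frame(
                               x = c(3, 7, 5), y = c(3, 7, 8),
                               weight = c(0.4, 0.4, 0.2), spread = c(1.2, 1.2, 0.8)),
                             seasonal_amplitude = 1,
                             peak_day = 15,
                             seasonal_mode = c("all", "controls-only"),
                             baseline_case_odds = 0.25,
                             age_distribution = c(mean = 35, sd = 22, min = 0, max = 106),
                             age_log_or = 0,
                             hotspots = list(),
                             hotspot_shape = c("disc", "gaussian"),
                             seed = 1L) {
  seasonal_mode <- match.arg(seasonal_mode)
  hotspot_shape <- match.arg(hotspot_shape)
  stopifnot(n_records >= 1, study_days >= 1,
            length(bbox) == 4, bbox[2] > bbox[1], bbox[4] > bbox[3],
            is.data.frame(population_clusters),
            all(c("x", "y", "weight", "spread") %in% names(population_clusters)),
            all(population_clusters$weight > 0),
            all(population_clusters$spread > 0),
            seasonal_amplitude > 0, baseline_case_odds > 0,
            length(age_distribution) == 4)
  population_clusters$weight <-
    population_clusters$weight / sum(population_clusters$weight)
  ad <- as.numeric(age_distribution)
  names(ad) <- c("mean", "sd", "min", "max")
  stopifnot(ad["sd"] > 0, ad["max"] > ad["min"])
  for (h in hotspots) {
    if (!inherits(h, "ed_hotspot")) stop("hotspots must be hotspot() objects")
    if (h$active_days[1] > study_days)
      stop("hotspot active interval starts after the study period")
  }
  structure(list(n_records = as.integer(n_records),
                 study_days = as.integer(study_days), bbox = bbox,
                 population_clusters = population_clusters,
                 seasonal_amplitude = seasonal_amplitude, peak_day = peak_day,
                 seasonal_mode = seasonal_mode,
                 baseline_case_odds = baseline_case_odds,
                 age_distribution = ad, age_log_or = age_log_or,
                 hotspots = hotspots, hotspot_shape = hotspot_shape,
                 seed = as.integer(seed)),
            class = "ed_synth_config")
}

#' @export
print.ed_synth_config <- function(x, ...) {
  cat("synthetic ED stream config: n =", x$n_records, "over", x$study_days,
      "days,", nrow(x$population_clusters), "population cluster(s),",
      length(x$hotspots), "hotspot(s)\n")
  cat(sprintf("baseline case odds %.3f, age effect %g/yr, seasonal ratio %g (%s), seed %d\n",
              x$baseline_case_odds, x$age_log_or, x$seasonal_amplitude,
              x$seasonal_mode, x$seed))
  invisible(x)
}

# seasonal visit intensity over study days: winter-peaked sinusoid whose
# peak/trough ratio equals the configured amplitude
seasonal_intensity <- function(config) {
  d <- seq_len(config$study_days)
  a <- (config$seasonal_amplitude - 1) / (config$seasonal_amplitude + 1)
  1 + a * cos(2 * pi * (d - config$peak_day) / 365.25)
}

# hotspot log-odds contribution at points (x, y) on a given day
hotspot_contribution <- function(config, x, y, day) {
  out <- numeric(length(x))
  for (h in config$hotspots) {
    active <- day >= h$active_days[1] & day <= h$active_days[2]
    d2 <- (x - h$center[1])^2 + (y - h$center[2])^2
    out <- out + if (config$hotspot_shape == "disc") {
      h$log_or * as.numeric(active & d2 < h$radius^2)
    } else {
      h$log_or * exp(-d2 / (2 * h$radius^2)) * as.numeric(active)
    }
  }
  out
}

#' Generate a synthetic ED dataset with known risk structure
#'
#' Draws a dataset from a [synthetic_config()] description. The returned
#' [ed_dataset()] carries a `truth` attribute: the config plus each record's
#' generative case probability, so every test of the analysis modules can be
#' scored against ground truth.
#'
#' @param config an [synthetic_config()] object.
#' @param seed optional override of `config$seed`.
#' @return an [ed_dataset()] with columns `x`, `y`, `day`, `outcome`, `age`
#'   and attribute `truth` (list: `config`, `p` — the per-record Bernoulli
#'   probability in generation order after day-sorting).
#' @examples
#' d <- generate_dataset(synthetic_config(n_records = 200, seed = 7))
#' mean(d$outcome)
#' @export
generate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "ed_synth_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  with_seed(seed, {
    n <- config$n_records
    intensity <- seasonal_intensity(config)
    day <- sample.int(config$study_days, n, replace = TRUE,
                      prob = intensity / sum(intensity))
    cl <- sample.int(nrow(config$population_clusters), n, replace = TRUE,
                     prob = config$population_clusters$weight)
    cx <- config$population_clusters$x[cl]
    cy <- config$population_clusters$y[cl]
    sp <- config$population_clusters$spread[cl]
    x <- pmin(pmax(cx + stats::rnorm(n, 0, sp), config$bbox[1]), config$bbox[2])
    y <- pmin(pmax(cy + stats::rnorm(n, 0, sp), config$bbox[3]), config$bbox[4])
    ad <- config$age_distribution
    age <- pmin(pmax(stats::rnorm(n, ad["mean"], ad["sd"]), ad["min"]), ad["max"])
    logit <- log(config$baseline_case_odds) +
      config$age_log_or * (age - ad[["mean"]]) +
      hotspot_contribution(config, x, y, day)
    p <- stats::plogis(logit)
    outcome <- stats::rbinom(n, 1L, p)
    if (config$seasonal_mode == "controls-only") {
      # controls' visit days follow the seasonal intensity; cases' are uniform
      # (redraw decouples control timing from the risk surface by design)
      idx <- outcome == 0L
      day[idx] <- sample.int(config$study_days, sum(idx), replace = TRUE,
                             prob = intensity / sum(intensity))
      day[!idx] <- sample.int(config$study_days, sum(!idx), replace = TRUE)
    }
    df <- data.frame(x = x, y = y, day = day, outcome = outcome, age = age)
    ord <- order(df$day)
    d <- ed_dataset(df, covariates = "age")
    attr(d, "truth") <- list(config = config, p = p[ord], cluster = cl[ord])
    d
  })
}

#' True odds-ratio surface of a synthetic configuration
#'
#' The generative reference: exp of the summed active hotspot contributions at
#' each grid point on the given day; 1 outside all hotspots.
#'
#' @param config a [synthetic_config()].
#' @param grid a [make_grid()] object, or a data.frame/matrix with `x`, `y`.
#' @param day study day at which to evaluate transient hotspots.
#' @return numeric vector of true ORs, one per grid point.
#' @export
true_or_surface <- function(config, grid, day = 1) {
  pts <- if (inherits(grid, "ed_grid")) grid$points else
    as.data.frame(as.matrix(grid))
  if (!all(c("x", "y") %in% names(pts))) names(pts)[1:2] <- c("x", "y")
  exp(hotspot_contribution(config, pts$x, pts$y, rep(day, nrow(pts))))
}

#' A Cape-Cod-scale default configuration
#'
#' A packaged synthetic stand-in at the scale of a five-year, three-hospital
#' ED surveillance stream: 44,421 records over 1,826 days, case fraction near
#' 0.16, coastal-style population clusters, winter-peaked visit seasonality,
#' one persistent east-side elevation and two transient hotspots. It sets
#' realistic magnitudes only; it does not (and cannot) reproduce any real
#' dataset, whose locations are confidential.
#'
#' @param n_records,seed overrides for quick small-scale runs.
#' @export
cape_cod_like_config <- function(n_records = 44421L, seed = 1L) {
  synthetic_config(
    n_records = n_records,
    study_days = 1826L,
    bbox = c(0, 40, 0, 25),
    population_clusters = data.frame(
      x = c(5, 12, 20, 28, 34),
      y = c(6, 10, 8, 14, 20),
      weight = c(0.25, 0.25, 0.2, 0.2, 0.1),
      spread = c(3, 3, 2.5, 2.5, 2)),
    seasonal_amplitude = 2,
    peak_day = 15,
    baseline_case_odds = 7111 / 37310,
    age_distribution = c(mean = 33, sd = 24, min = 0, max = 106),
    age_log_or = 0.002,
    hotspots = list(
      hotspot(center = c(30, 14), radius = 5, log_or = log(1.5)),
      hotspot(center = c(10, 9), radius = 3, log_or = log(2),
              active_days = c(400, 520)),
      hotspot(center = c(21, 7), radius = 3, log_or = log(2),
              active_days = c(1100, 1250))),
    seed = seed)
}

# evaluate expr under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
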