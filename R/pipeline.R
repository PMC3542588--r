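#' Pipeline configuration
#'
#' Tunable parameters of the per-window space-time analysis. Defaults follow
#' standard practice for this family of analyses: a 50 x 50 prediction grid,
#' 999 permutations, a conservative 0.005 global screening cutoff (chosen for
#' the multiplicity of per-window tests), 2.5%/97.5% pointwise flag tails, and
#' 0.5 s per animation frame.
#'
#' @param candidate_spans spans tried by per-window AIC selection.
#' @param nx,ny prediction-grid resolution.
#' @param mask optional study-area polygon ([read_mask()] result or ring list).
#' @param max_mask_distance drop grid points without `mask_min_points` records
#'   within this distance (low-population edges); `Inf` keeps all.
#' @param mask_min_points records required within `max_mask_distance`.
#' @param n_perm permutations per window (>= 39; the global screen at
#'   `screening_p` needs `1/(n_perm+1) < screening_p`).
#' @param screening_p global p-value cutoff gating the pointwise flags.
#' @param temporal_span,window_span framing spans; `NULL` selects them by AIC
#'   from `candidate_spans` (whole dataset, then first window).
#' @param covariates parametric adjustment columns (default: dataset's).
#' @param seed master seed; per-window permutation seeds derive from it.
#' @param frame_duration_s seconds each map frame plays in the animation.
#' @param max_iter,tol local-scoring controls.
#' @export
pipeline_config <- function(candidate_spans = default_spans(),
                            nx = 50, ny = 50,
                            mask = NULL, max_mask_distance = Inf,
                            mask_min_points = 1L,
                            n_perm = 999, screening_p = 0.005,
                            temporal_span = NULL, window_span = NULL,
                            covariates = NULL, seed = 1L,
                            frame_duration_s = 0.5,
                            max_iter = 50L, tol = 1e-6) {
  stopifnot(length(candidate_spans) >= 1, all(candidate_spans > 0),
            all(candidate_spans <= 1), n_perm >= 39,
            screening_p > 0, screening_p < 1, frame_duration_s > 0)
  structure(list(candidate_spans = candidate_spans, nx = nx, ny = ny,
                 mask = mask, max_mask_distance = max_mask_distance,
                 mask_min_points = as.integer(mask_min_points),
                 n_perm = as.integer(n_perm), screening_p = screening_p,
                 temporal_span = temporal_span, window_span = window_span,
                 covariates = covariates, seed = as.integer(seed),
                 frame_duration_s = frame_duration_s,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "ed_pipeline_config")
}

#' Odds-ratio surface relative to the whole-window reference
#'
#' Converts predicted adjusted log odds to odds ratios with the whole study
#' population as reference: the full model's predicted odds at each grid
#' point, divided by the odds from the reduced model omitting the smooth term,
#' both evaluated at the covariate reference `z_ref`. With the smooth term
#' identically zero and matching parametric coefficients the surface is 1
#' everywhere.
#'
#' @param full an [edgam()] spatial fit.
#' @param reduced the matching [fit_parametric_logistic()] fit (defaults to
#'   the one stored in `full`).
#' @param grid an [make_grid()] object (only active points are predicted) or
#'   a matrix/data.frame of points.
#' @param z_ref covariate reference vector; default the window covariate mean.
#' @return numeric vector of ORs (NA at masked/empty-neighbourhood points),
#'   one per grid point (full grid length when `grid` is an `ed_grid`).
#' @export
odds_ratio_map <- function(full, reduced = full$reduced, grid, z_ref = NULL) {
  stopifnot(inherits(full, "edgam"), full$smooth_type == "space")
  if (is.null(z_ref)) z_ref <- full$z_mean
  if (inherits(grid, "ed_grid")) {
    pts <- as.matrix(grid$points[, c("x", "y")])
    or <- rep(NA_real_, nrow(pts))
    act <- grid$active
  } else {
    pts <- as.matrix(grid)
    or <- rep(NA_real_, nrow(pts))
    act <- rep(TRUE, nrow(pts))
  }
  lo_full <- predict(full, pts[act, , drop = FALSE], z_ref = z_ref)
  lo_red <- reduced$intercept + sum(reduced$gamma * z_ref)
  or[act] <- exp(lo_full - lo_red)
  or
}

#' Analyze one time window
#'
#' The per-window spatial analysis: select the span by AIC, fit the
#' age-adjusted spatial GAM and its reduced model, predict the odds-ratio
#' surface on the active grid points, run the global deviance permutation
#' test, and compute pointwise permutation ranks from the same permutation
#' set. Hot/cold flags are populated only when the global p-value passes the
#' screening cutoff (gatekeeping). A degenerate window (single outcome class)
#' returns an `ORMap` with an error status rather than failing, so a pipeline
#' over many windows can continue.
#'
#' @param data the full [ed_dataset()].
#' @param window an `ed_window` (from [build_framing()]); or `NULL` to treat
#'   the whole dataset as one window.
#' @param grid a masked [make_grid()] shared across windows.
#' @param config an [pipeline_config()].
#' @param seed permutation seed for this window (default derived from
#'   `config$seed` and the window id).
#' @return object of class `ed_ormap`: per-grid-point `or`, `log_odds`,
#'   `rank_pct`, `flag`; `global_p`, `span`, `window_id`, `median_day`,
#'   `status`, counts of hot/cold points.
#' @export
analyze_window <- function(data, window = NULL, grid, config = pipeline_config(),
                           seed = NULL) {
  if (!inherits(data, "ed_dataset")) data <- ed_dataset(data)
  if (is.null(window)) window <- new_window(data, 1L, nrow(data), 1L)
  wdata <- data[window$indices, , drop = FALSE]
  attr(wdata, "covariates") <- ed_covariates(data)
  class(wdata) <- class(data)
  if (is.null(seed)) seed <- window_seed(config$seed, window$window_id)
  npt <- nrow(grid$points)
  base <- list(window_id = window$window_id, median_day = window$median_day,
               first_day = window$first_day, last_day = window$last_day,
               n = window$length, grid = grid,
               or = rep(NA_real_, npt), log_odds = rep(NA_real_, npt),
               rank_pct = rep(NA_real_, npt),
               flag = rep(NA_character_, npt),
               span = NA_real_, global_p = NA_real_, observed_stat = NA_real_,
               n_hot = 0L, n_cold = 0L, seed = seed, status = "ok",
               screening_p = config$screening_p)
  res <- tryCatch({
    cov <- config$covariates %||% ed_covariates(wdata)
    sel <- select_span(wdata, "space", config$candidate_spans, cov,
                       config$max_iter, config$tol)
    gt <- global_test(wdata, sel$span, config$n_perm, seed, cov,
                      grid = grid, max_iter = config$max_iter,
                      tol = config$tol)
    act <- grid$active
    lo <- rep(NA_real_, npt)
    lo[act] <- gt$observed_surface
    red <- gt$reduced$intercept + sum(gt$reduced$gamma * gt$z_ref)
    base$or <- exp(lo - red)
    base$log_odds <- lo
    base$span <- sel$span
    base$aic_table <- sel$aic_table
    base$global_p <- gt$p_value
    base$observed_stat <- gt$observed_stat
    rk <- pointwise_ranks(gt$observed_surface, gt$perm_surfaces)
    base$rank_pct[act] <- rk$rank_pct
    if (gt$p_value < config$screening_p) {
      base$flag[act] <- rk$flag
    } else {
      base$flag[act] <- "none"       # gatekeeping: no flags without a global signal
    }
    base$n_hot <- sum(base$flag == "hot", na.rm = TRUE)
    base$n_cold <- sum(base$flag == "cold", na.rm = TRUE)
    base$z_ref <- gt$z_ref
    base
  }, error = function(e) {
    base$status <- paste0("error: ", conditionMessage(e))
    base
  })
  structure(res, class = "ed_ormap")
}

window_seed <- function(seed, window_id) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(window_id) * 69621) %% 2147483629)
}

#' @export
print.ed_ormap <- function(x, ...) {
  cat(sprintf("OR map, window %s (median day %s, n = %d): ",
              x$window_id, x$median_day, x$n))
  if (x$status != "ok") {
    cat(x$status, "\n")
  } else {
    cat(sprintf("span %.3g, global p = %.4g, OR range [%.3g, %.3g], %d hot / %d cold\n",
                x$span, x$global_p, min(x$or, na.rm = TRUE),
                max(x$or, na.rm = TRUE), x$n_hot, x$n_cold))
  }
  invisible(x)
}

#' Run the full space-time analysis
#'
#' End to end: build (or accept) the overlapping-window framing, build and
#' mask one shared prediction grid, analyze every window with
#' [analyze_window()], pool the odds ratios into one shared display range
#' (symmetric in log OR, clipped at the pooled 1st/99th percentiles), and
#' tabulate a per-window summary. Window failures are recorded in the summary
#' (`status`), not fatal.
#'
#' @param data an [ed_dataset()].
#' @param config an [pipeline_config()].
#' @param framing optional precomputed [build_framing()] result.
#' @return object of class `ed_stmap`: `maps` (list of `ed_ormap`), `summary`
#'   (data.frame), `or_range`, `framing`, `grid`, `config`.
#' @export
run_pipeline <- function(data, config = pipeline_config(), framing = NULL) {
  if (!inherits(data, "ed_dataset")) data <- ed_dataset(data)
  cov <- config$covariates %||% ed_covariates(data)
  if (is.null(framing)) {
    ts <- config$temporal_span %||%
      select_span(data, "time", config$candidate_spans, cov,
                  config$max_iter, config$tol)$span
    L <- optimal_window_length(nrow(data), ts)
    w1 <- first_window(data, L)
    ws <- config$window_span
    if (is.null(ws)) {
      w1data <- data[w1$indices, , drop = FALSE]
      attr(w1data, "covariates") <- cov
      class(w1data) <- class(data)
      ws <- select_span(w1data, "time", config$candidate_spans, cov,
                        config$max_iter, config$tol)$span
    }
    framing <- build_framing(data, ts, ws)
  }
  grid <- make_grid(data, config$nx, config$ny)
  grid <- apply_mask(grid, config$mask, data, config$max_mask_distance,
                     config$mask_min_points)
  maps <- lapply(framing$windows, function(w)
    analyze_window(data, w, grid, config))
  pooled <- unlist(lapply(maps, function(m) m$or))
  pooled <- pooled[is.finite(pooled) & pooled > 0]
  or_range <- if (length(pooled)) {
    q <- stats::quantile(log(pooled), c(0.01, 0.99), names = FALSE)
    mm <- max(abs(q))
    exp(c(-mm, mm))
  } else c(1 / 2, 2)
  summary <- do.call(rbind, lapply(maps, function(m)
    data.frame(window_id = m$window_id, median_day = m$median_day,
               first_day = m$first_day, last_day = m$last_day, n = m$n,
               span = m$span, global_p = m$global_p,
               n_hot = m$n_hot, n_cold = m$n_cold, status = m$status)))
  structure(list(maps = maps, summary = summary, or_range = or_range,
                 framing = framing, grid = grid, config = config),
            class = "ed_stmap")
}

#' @export
print.ed_stmap <- function(x, ...) {
  cat(sprintf("space-time OR map series: %d window(s), shared OR display range [%.3g, %.3g]\n",
              length(x$maps), x$or_range[1], x$or_range[2]))
  nsig <- sum(x$summary$global_p < x$config$screening_p, na.rm = TRUE)
  cat(sprintf("%d window(s) pass the global %g screen\n", nsig,
              x$config$screening_p))
  print(utils::head(x$summary, 10))
  if (nrow(x$summary) > 10) cat("...\n")
  invisible(x)
}
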