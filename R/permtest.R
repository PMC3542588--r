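# deterministic permutation of 1..n from (seed, perm_index), without
# disturbing the caller's RNG stream
perm_indices <- function(n, seed, perm_index) {
  s <- (as.numeric(seed) %% 2147483647) * 69621 + as.numeric(perm_index)
  with_seed(as.integer(s %% 2147483647), sample.int(n))
}

#' Conditionally permute record locations within a window
#'
#' Randomly reassigns the `(x, y)` pairs among the window's records while day,
#' outcome and covariates stay attached to their records. This breaks only the
#' location-outcome link given the covariates — the null hypothesis of a flat
#' map — and is the permutation scheme behind both the global deviance test
#' and the pointwise ranks. Deterministic given `(seed, perm_index)`.
#'
#' @param data an [ed_dataset()] (typically one window's records).
#' @param seed integer seed shared by a whole permutation set.
#' @param perm_index which permutation of the set (1, 2, ...).
#' @return the dataset with permuted coordinates; attribute `perm` holds the
#'   permutation used (`x[i] <- x[perm[i]]`).
#' @export
permute_window <- function(data, seed, perm_index = 1L) {
  if (!inherits(data, "ed_dataset")) data <- ed_dataset(data)
  p <- perm_indices(nrow(data), seed, perm_index)
  out <- data
  out$x <- data$x[p]
  out$y <- data$y[p]
  attr(out, "perm") <- p
  out
}

#' Global deviance permutation test of map flatness
#'
#' Tests the null hypothesis that case status does not depend on location:
#' the statistic is `deviance(reduced) - deviance(full)` at the window's
#' selected span, and its null distribution is estimated by refitting the GAM
#' (at the same span) to conditionally permuted data. The p-value is
#' `(1 + #permuted >= observed) / (n_perm + 1)`, so its floor is
#' `1 / (n_perm + 1)`.
#'
#' @param data an [ed_dataset()] window.
#' @param span the window's selected span (permuted fits reuse it).
#' @param n_perm number of permutations (>= 39; >= 200 for a 0.005 screen).
#' @param seed integer seed; permutations come from [permute_window()]'s
#'   scheme with `perm_index = 1..n_perm`.
#' @param covariates parametric adjustment columns.
#' @param grid optional [make_grid()]; when supplied, each permuted fit also
#'   predicts the adjusted log odds on the active grid points so
#'   [pointwise_ranks()] can reuse the same permutation set.
#' @param z_ref covariate reference for grid predictions (default window
#'   means).
#' @param max_iter,tol local-scoring controls.
#' @return object of class `ed_global_test`: `observed_stat`, `perm_stats`,
#'   `p_value`, `n_perm`, `seed`, `fit` (the observed full fit), `reduced`,
#'   `observed_surface` and `perm_surfaces` when a grid was given.
#' @export
global_test <- function(data, span, n_perm = 999, seed = 1L,
                        covariates = NULL, grid = NULL, z_ref = NULL,
                        max_iter = 50L, tol = 1e-6) {
  if (!inherits(data, "ed_dataset")) data <- ed_dataset(data)
  if (n_perm < 39) stop("n_perm must be at least 39", call. = FALSE)
  if (is.null(covariates)) covariates <- ed_covariates(data)
  fit <- edgam(data, "space", span, covariates, max_iter, tol)
  reduced <- fit$reduced
  observed <- reduced$deviance - fit$deviance
  n <- nrow(data)
  if (is.null(z_ref)) z_ref <- fit$z_mean

  # permuting coordinates among records == inversely permuting (outcome,
  # covariates) against the fixed coordinate set; the latter reuses the
  # precomputed neighbourhood plan
  perm <- vapply(seq_len(n_perm),
                 function(b) order(perm_indices(n, seed, b)), integer(n))
  X <- fit$coords
  Z <- as.matrix(as.data.frame(data)[, covariates, drop = FALSE])
  pl <- loess_plan_cpp(X, X, span)
  want_surf <- !is.null(grid)
  if (want_surf) {
    G <- as.matrix(grid$points[grid$active, c("x", "y")])
    gpl <- loess_plan_cpp(X, G, span)
  } else {
    G <- matrix(numeric(), 0, 2)
    gpl <- list(idx = matrix(integer(), 0, 0), kw = matrix(numeric(), 0, 0),
                bw = numeric())
  }
  pr <- gam_perm_cpp(X, pl$idx, pl$kw, pl$bw, Z, as.numeric(data$outcome),
                     c(reduced$intercept, reduced$gamma), reduced$deviance,
                     perm - 1L, G, gpl$idx, gpl$kw, gpl$bw,
                     as.numeric(z_ref), want_surf,
                     as.integer(max_iter), tol)
  if (pr$n_nonconverged > 0)
    warning(pr$n_nonconverged, " permuted fit(s) did not converge; ",
            "their statistics are retained")
  stats <- as.numeric(pr$stats)
  p <- (1 + sum(stats >= observed)) / (n_perm + 1)
  out <- list(observed_stat = observed, perm_stats = stats, p_value = p,
              n_perm = n_perm, seed = seed, fit = fit, reduced = reduced,
              z_ref = z_ref)
  if (want_surf) {
    out$observed_surface <- predict(fit, G, z_ref = z_ref)
    out$perm_surfaces <- pr$surfaces       # (active points) x n_perm
  }
  structure(out, class = "ed_global_test")
}

#' @export
print.ed_global_test <- function(x, ...) {
  cat(sprintf("global deviance permutation test: stat = %.3f, p = %.4g (%d permutations)\n",
              x$observed_stat, x$p_value, x$n_perm))
  invisible(x)
}

#' Pointwise permutation ranks and hot/cold flags
#'
#' For each grid point, the percentile rank of the observed adjusted log odds
#' within the permutation distribution (mid-rank tie handling): `100 *
#' (#below + 0.5 * #ties) / n_perm`. Points above the 97.5th percentile are
#' flagged `hot`, below the 2.5th `cold`. Flags should only be acted on when
#' the window's global test passes the screening cutoff (gatekeeping is
#' applied by [analyze_window()]).
#'
#' @param observed numeric vector of observed log odds per grid point.
#' @param perm_surfaces matrix (points x permutations) of permuted log odds.
#' @param lower,upper flag thresholds in percent.
#' @return data.frame with `rank_pct` and `flag` (`"hot"`, `"cold"`,
#'   `"none"`; `NA` observations stay `NA`).
#' @export
pointwise_ranks <- function(observed, perm_surfaces,
                            lower = 2.5, upper = 97.5) {
  stopifnot(length(observed) == nrow(perm_surfaces))
  B <- ncol(perm_surfaces)
  below <- rowSums(perm_surfaces < observed, na.rm = TRUE)
  ties <- rowSums(perm_surfaces == observed, na.rm = TRUE)
  rank_pct <- 100 * (below + 0.5 * ties) / B
  flag <- ifelse(rank_pct > upper, "hot",
                 ifelse(rank_pct < lower, "cold", "none"))
  rank_pct[is.na(observed)] <- NA_real_
  flag[is.na(observed)] <- NA_character_
  data.frame(rank_pct = rank_pct, flag = flag)
}
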