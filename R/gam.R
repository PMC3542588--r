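#' Fit a loess-logistic generalized additive model
#'
#' Fits `logit p = S(coords) + intercept + gamma' z` to case-control records,
#' where `S` is a tri-cube locally weighted local-linear (loess) smooth of
#' either location (`smooth = "space"`, bivariate over `x, y`) or time
#' (`smooth = "time"`, univariate over study day), and `z` holds parametric
#' covariates (by default the dataset's covariates, e.g. age). Estimation is by
#' local scoring: starting from the covariate-only logistic fit, each iteration
#' forms the working response and weights, backfits a weighted parametric solve
#' and a loess smooth of the partial residuals, and re-centres the smooth to
#' weighted mean zero (the centring constant is absorbed into the intercept for
#' identifiability). Iteration stops when the relative deviance change falls
#' below `tol` or after `max_iter` iterations; the best-deviance iterate is
#' retained, so the fit never has larger deviance than the covariate-only
#' model it nests.
#'
#' The effective degrees of freedom are the parametric count plus the smoother
#' trace minus one (the centring constraint); `aic = deviance + 2 * edf`, the
#' deviance-based approximation to cross-validation used for span selection.
#'
#' @param data an [ed_dataset()] (or data.frame coercible to one).
#' @param smooth `"space"` or `"time"`: which coordinates the smooth term uses.
#' @param span fraction of records in each local window, in (0, 1].
#' @param covariates covariate column names to adjust for parametrically;
#'   defaults to the dataset's covariates.
#' @param max_iter,tol local-scoring iteration cap and relative-deviance
#'   convergence tolerance.
#' @return Object of class `edgam`: coefficients, centred smooth values
#'   `smooth` at the records, `deviance`, `edf`, `aic`, `span`, convergence
#'   information, the reduced (covariate-only) fit, and the final working
#'   residuals and weights used by [predict.edgam()].
#' @examples
#' set.seed(1)
#' cfg <- synthetic_config(n_records = 400, study_days = 30, seed = 1)
#' d <- generate_dataset(cfg)
#' f <- edgam(d, smooth = "space", span = 0.7)
#' f
#' @seealso [select_span()], [fit_parametric_logistic()], [predict.edgam()]
#' @export
edgam <- function(data, smooth = c("space", "time"), span,
                  covariates = NULL, max_iter = 50L, tol = 1e-6) {
  if (!inherits(data, "ed_dataset")) data <- ed_dataset(data)
  smooth <- match.arg(smooth)
  check_span(span)
  if (is.null(covariates)) covariates <- ed_covariates(data)
  y <- data$outcome
  if (all(y == 1L) || all(y == 0L))
    stop("degenerate window: all records are ",
         if (all(y == 1L)) "cases" else "controls",
         " (days ", data$day[1], "-", data$day[nrow(data)], ")", call. = FALSE)
  X <- ed_coords(data, smooth)
  Z <- as.matrix(as.data.frame(data)[, covariates, drop = FALSE])
  reduced <- fit_parametric_logistic(y, Z)
  n <- nrow(X)
  k <- ceiling(span * n)
  if (k < ncol(X) + 2L)
    stop("span ", span, " gives a local window of ", k,
         " points; too few for a local-linear fit", call. = FALSE)
  pl <- loess_plan_cpp(X, X, span)
  ft <- gam_fit_cpp(X, pl$idx, pl$kw, pl$bw, Z, as.numeric(y),
                    c(reduced$intercept, reduced$gamma),
                    as.integer(max_iter), tol, TRUE)
  if (!ft$converged)
    warning("local scoring did not converge in ", max_iter,
            " iterations; best iterate returned")
  gamma <- as.numeric(ft$gamma)
  names(gamma) <- covariates
  eta <- ft$intercept + as.numeric(ft$S) +
    (if (length(gamma)) drop(Z %*% gamma) else 0)
  edf <- (1L + length(gamma)) + (ft$trace - 1)
  structure(list(
    coefficients = c("(Intercept)" = ft$intercept, gamma),
    intercept = ft$intercept, gamma = gamma,
    smooth = as.numeric(ft$S),
    deviance = ft$deviance, edf = edf, aic = ft$deviance + 2 * edf,
    trace = ft$trace, span = span, smooth_type = smooth,
    converged = isTRUE(ft$converged), n_iter = ft$n_iter,
    n_fallback = ft$n_fallback,
    reduced = reduced,
    working = list(residual = as.numeric(ft$r), weights = as.numeric(ft$w)),
    coords = X, covariates = covariates, eta = eta,
    z_mean = if (length(covariates)) colMeans(Z) else numeric(),
    n = n, y = y, call = match.call()),
    class = "edgam")
}

#' Covariate-only (reduced) logistic model
#'
#' Maximum-likelihood logistic regression of the outcome on the parametric
#' covariates alone — the model "without the smooth term". Its deviance is the
#' baseline of the global deviance statistic and its predicted odds are the
#' reference (denominator) of the mapped odds ratios. Fitting is IRLS via
#' [stats::glm.fit()].
#'
#' @param outcome binary 0/1 vector.
#' @param covariates numeric matrix (may have zero columns for an
#'   intercept-only model).
#' @return object of class `edgam_reduced`: `intercept`, `gamma`, `deviance`,
#'   `df` (number of coefficients), `converged`.
#' @examples
#' fit_parametric_logistic(rep(c(0, 1), c(50, 50)), matrix(numeric(), 100, 0))
#' @export
fit_parametric_logistic <- function(outcome, covariates = NULL) {
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (is.null(covariates)) covariates <- matrix(numeric(), length(y), 0)
  Z <- as.matrix(covariates)
  D <- cbind("(Intercept)" = rep(1, length(y)), Z)
  if (qr(D)$rank < ncol(D)) stop("covariate design is rank deficient", call. = FALSE)
  ft <- suppressWarnings(stats::glm.fit(D, y, family = stats::binomial()))
  if (!ft$converged) warning("reduced logistic fit did not converge (possible separation)")
  co <- ft$coefficients
  structure(list(intercept = unname(co[1]),
                 gamma = if (ncol(Z)) stats::setNames(unname(co[-1]), colnames(Z)) else numeric(),
                 deviance = ft$deviance, df = ncol(D),
                 converged = ft$converged),
            class = "edgam_reduced")
}

#' @export
print.edgam_reduced <- function(x, ...) {
  cat("parametric logistic (reduced) model: deviance =",
      format(x$deviance, digits = 6), " df =", x$df, "\n")
  print(c("(Intercept)" = x$intercept, x$gamma))
  invisible(x)
}

#' AIC from deviance and effective degrees of freedom
#'
#' `deviance + 2 * edf`; within one dataset this ranks candidate spans
#' identically to the per-observation (average-deviance) form.
#'
#' @param deviance nonnegative model deviance.
#' @param edf nonnegative effective degrees of freedom.
#' @export
gam_aic <- function(deviance, edf) {
  stopifnot(deviance >= 0, edf >= 0)
  deviance + 2 * edf
}

#' Select the smoothing span by AIC
#'
#' Fits the GAM at each candidate span and returns the AIC-minimizing one
#' ("the statistically optimal degree of smoothing"). Ties are broken toward
#' the larger span, i.e. the smoother map.
#'
#' @inheritParams edgam
#' @param candidate_spans numeric vector of spans in (0, 1].
#' @return list with `span` (the selection), `aic_table` (data.frame of span,
#'   aic, deviance, edf, converged), `fit` (the refitted winner).
#' @examples
#' cfg <- synthetic_config(n_records = 300, study_days = 30, seed = 2)
#' d <- generate_dataset(cfg)
#' select_span(d, "space", candidate_spans = c(0.5, 0.9))$span
#' @export
select_span <- function(data, smooth = c("space", "time"),
                        candidate_spans = default_spans(),
                        covariates = NULL, max_iter = 50L, tol = 1e-6) {
  smooth <- match.arg(smooth)
  if (!length(candidate_spans)) stop("no candidate spans", call. = FALSE)
  fits <- lapply(candidate_spans, function(s) {
    tryCatch(edgam(data, smooth, s, covariates, max_iter, tol),
             error = function(e) e)
  })
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok))
    stop("all candidate spans failed: ",
         paste(sprintf("%g (%s)", candidate_spans,
                       vapply(fits, conditionMessage, character(1))),
               collapse = "; "), call. = FALSE)
  aics <- vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else f$aic,
                 numeric(1))
  tab <- data.frame(span = candidate_spans, aic = aics,
                    deviance = vapply(fits, function(f)
                      if (inherits(f, "error")) NA_real_ else f$deviance, numeric(1)),
                    edf = vapply(fits, function(f)
                      if (inherits(f, "error")) NA_real_ else f$edf, numeric(1)),
                    converged = vapply(fits, function(f)
                      if (inherits(f, "error")) NA else f$converged, logical(1)))
  best <- min(aics, na.rm = TRUE)
  cand <- which(!is.na(aics) & aics <= best + 1e-9)
  pick <- cand[which.max(candidate_spans[cand])]   # tie -> larger span
  list(span = candidate_spans[pick], aic_table = tab, fit = fits[[pick]])
}

#' Default candidate spans
#'
#' A fine low end (temporal optima can be as small as a few percent of the
#' data) plus a coarse ladder to full-data smoothing.
#' @export
default_spans <- function() c(seq(0.02, 0.10, by = 0.01), seq(0.15, 0.95, by = 0.05))

#' Predict adjusted log odds at new points
#'
#' Evaluates the smooth term at each new point by the same tri-cube
#' local-linear fit applied to the stored working residuals and weights of the
#' final scoring iteration, and adds the parametric part at the reference
#' covariate vector `z_ref` (default: the covariate means of the fitting
#' window). Points with an empty effective neighbourhood come back `NA`.
#'
#' @param object an [edgam()] fit.
#' @param newdata matrix or data.frame of prediction points: columns `x`, `y`
#'   for a spatial fit, `day` for a temporal one (or a bare matrix in fit
#'   coordinate order).
#' @param z_ref covariate reference vector (recycled names must match).
#' @param ... unused.
#' @return numeric vector of adjusted log odds.
#' @export
predict.edgam <- function(object, newdata, z_ref = NULL, ...) {
  Tm <- prediction_points(object, newdata)
  if (is.null(z_ref)) z_ref <- object$z_mean
  if (length(z_ref) != length(object$gamma))
    stop("z_ref must have ", length(object$gamma), " element(s)", call. = FALSE)
  pl <- loess_plan_cpp(object$coords, Tm, object$span)
  ap <- loess_apply_cpp(object$coords, Tm, pl$idx, pl$kw, pl$bw,
                        object$working$residual, object$working$weights,
                        rep(-1L, nrow(Tm)), FALSE)
  as.numeric(ap$fitted) + object$intercept + sum(object$gamma * z_ref)
}

prediction_points <- function(object, newdata) {
  want <- if (object$smooth_type == "space") c("x", "y") else "day"
  if (is.data.frame(newdata)) {
    if (!all(want %in% names(newdata)))
      stop("newdata must have column(s): ", paste(want, collapse = ", "),
           call. = FALSE)
    as.matrix(newdata[, want, drop = FALSE])
  } else {
    m <- as.matrix(newdata)
    if (ncol(m) != length(want))
      stop("newdata must have ", length(want), " column(s)", call. = FALSE)
    m
  }
}

#' @export
print.edgam <- function(x, digits = 4, ...) {
  cat("loess-logistic GAM (", x$smooth_type, " smooth), n = ", x$n,
      ", span = ", x$span, "\n", sep = "")
  print(round(x$coefficients, digits))
  cat(sprintf("deviance = %.*f  edf = %.2f  AIC = %.*f  (%s, %d iterations)\n",
              digits, x$deviance, x$edf, digits, x$aic,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' @export
summary.edgam <- function(object, ...) {
  s <- list(fit = object,
            deviance_reduced = object$reduced$deviance,
            deviance_explained = object$reduced$deviance - object$deviance,
            smooth_range = range(object$smooth))
  class(s) <- "summary.edgam"
  s
}

#' @export
print.summary.edgam <- function(x, ...) {
  print(x$fit)
  cat(sprintf("reduced-model deviance = %.4f (smooth term explains %.4f)\n",
              x$deviance_reduced, x$deviance_explained))
  cat(sprintf("centred smooth range at the records: [%.3f, %.3f] (log odds)\n",
              x$smooth_range[1], x$smooth_range[2]))
  invisible(x)
}

#' @export
coef.edgam <- function(object, ...) object$coefficients

#' @export
deviance.edgam <- function(object, ...) object$deviance

#' @export
logLik.edgam <- function(object, ...) {
  structure(-object$deviance / 2, df = object$edf, nobs = object$n,
            class = "logLik")
}

#' @export
residuals.edgam <- function(object, type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  if (type == "response") return(object$y - mu)
  d2 <- -2 * (object$y * log(pmax(mu, 1e-12)) +
                (1 - object$y) * log(pmax(1 - mu, 1e-12)))
  sign(object$y - mu) * sqrt(pmax(d2, 0))
}

#' @export
fitted.edgam <- function(object, ...) stats::plogis(object$eta)
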