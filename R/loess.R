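#' Tri-cube kernel weight
#'
#' The loess distance kernel: `(1 - u^3)^3` for scaled distances `u < 1` and 0
#' beyond the neighbourhood boundary. It down-weights points far from the
#' target, which keeps edge bias smaller than for flat nearest-neighbour
#' windows of the same span.
#'
#' @param u nonnegative scaled distance (distance / bandwidth); vectorized.
#' @return weights in `[0, 1]`.
#' @examples
#' tricube(c(0, 0.5, 1))
#' @export
tricube <- function(u) {
  if (any(u < 0)) stop("scaled distance must be nonnegative", call. = FALSE)
  ifelse(u < 1, (1 - u^3)^3, 0)
}

#' Span-based nearest neighbourhood
#'
#' Returns the `k = ceiling(span * n)` points nearest the target in Euclidean
#' distance, with ties at the boundary broken by original record order, and the
#' bandwidth (distance to the k-th neighbour) that scales the tri-cube kernel.
#'
#' @param coords numeric matrix (n x 1 or n x 2) of point coordinates; a vector
#'   is taken as one-dimensional coordinates.
#' @param target numeric vector, the target point.
#' @param span fraction of the data in the local window, in (0, 1].
#' @return list with `indices` (the k member row indices), `bandwidth`, `k`.
#' @examples
#' loess_neighborhood(matrix(1:10), target = 1, span = 0.3)
#' @export
loess_neighborhood <- function(coords, target, span) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop("no points", call. = FALSE)
  check_span(span)
  pl <- loess_plan_cpp(coords, matrix(target, nrow = 1), span)
  list(indices = as.integer(pl$idx[, 1]) + 1L,
       bandwidth = pl$bw[1], k = pl$k)
}

check_span <- function(span) {
  if (!is.numeric(span) || length(span) != 1L || is.na(span) ||
      span <= 0 || span > 1)
    stop("span must be a fraction in (0, 1]", call. = FALSE)
  invisible(span)
}

#' Local linear fit at one target point
#'
#' Weighted least squares of the response on `(1, coords - target)` over the
#' span-neighbourhood, with weight = prior weight x tri-cube(distance /
#' bandwidth). Returns the local intercept (the fitted value at the target)
#' together with the hat row: the linear functional of the response producing
#' it. A rank-deficient local design (e.g. all neighbours coincident) falls
#' back to the weighted mean with a warning.
#'
#' @inheritParams loess_neighborhood
#' @param response numeric response (working response in the GAM context).
#' @param weights nonnegative prior weights (default 1).
#' @return list with `fitted`, `hat_row` (length n, zero outside the
#'   neighbourhood), `indices`, `bandwidth`.
#' @export
local_linear_fit <- function(coords, response, target, span, weights = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(response) == n, length(weights) == n)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  nb <- loess_neighborhood(coords, target, span)
  idx <- nb$indices
  h <- if (nb$bandwidth > 0) nb$bandwidth else 1
  u <- sqrt(rowSums((coords[idx, , drop = FALSE] -
                       matrix(target, length(idx), ncol(coords), byrow = TRUE))^2)) / h
  w <- weights[idx] * tricube(pmin(u, 1))
  hat <- numeric(n)
  if (sum(w) <= 0) return(list(fitted = NA_real_, hat_row = hat,
                               indices = idx, bandwidth = nb$bandwidth))
  D <- cbind(1, sweep(coords[idx, , drop = FALSE], 2, target) / h)
  A <- crossprod(D, D * w)
  ok <- TRUE
  a1 <- tryCatch(solve(A, c(1, numeric(ncol(D) - 1L))),
                 error = function(e) { ok <<- FALSE; NULL })
  if (ok && rcond(A) > 1e-12) {
    hat[idx] <- as.numeric(D %*% a1) * w
  } else {
    warning("rank-deficient local design; falling back to weighted mean")
    hat[idx] <- w / sum(w)
  }
  list(fitted = sum(hat * response), hat_row = hat,
       indices = idx, bandwidth = nb$bandwidth)
}

#' Loess smooth of a response over 1-D or 2-D coordinates
#'
#' Applies the tri-cube local-linear fit at every data point. The returned
#' `trace` (sum of the hat diagonal) is the smoother's effective number of
#' parameters, used for the GAM's effective degrees of freedom and AIC.
#'
#' @inheritParams local_linear_fit
#' @return object of class `loess_fit`: list with `fitted`, `hat_diag`,
#'   `trace`, `span`, `k`, and the inputs needed by [predict.loess_fit()].
#' @examples
#' x <- seq(0, 1, length.out = 40)
#' f <- loess_smooth(x, sin(2 * pi * x), span = 0.5)
#' f$trace
#' @export
loess_smooth <- function(coords, response, span, weights = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(response) == n, length(weights) == n)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  check_span(span)
  pl <- loess_plan_cpp(coords, coords, span)
  ap <- loess_apply_cpp(coords, coords, pl$idx, pl$kw, pl$bw,
                        as.numeric(response), as.numeric(weights),
                        seq_len(n) - 1L, TRUE)
  if (ap$n_fallback > 0)
    warning(ap$n_fallback, " rank-deficient local fit(s); weighted-mean fallback used")
  structure(list(fitted = as.numeric(ap$fitted),
                 hat_diag = as.numeric(ap$hat_diag),
                 trace = sum(ap$hat_diag),
                 span = span, k = pl$k,
                 coords = coords, response = as.numeric(response),
                 weights = as.numeric(weights)),
            class = "loess_fit")
}

#' @export
print.loess_fit <- function(x, ...) {
  cat("loess local-linear smooth: n =", nrow(x$coords),
      "dim =", ncol(x$coords), "span =", x$span,
      sprintf("(k = %d), trace = %.2f\n", x$k, x$trace))
  invisible(x)
}

#' Evaluate a loess smooth at new points
#'
#' @param object a [loess_smooth()] fit.
#' @param newdata matrix of points (same dimension as the fit coordinates).
#' @param ... unused.
#' @return numeric vector; `NA` where the effective neighbourhood is empty.
#' @export
predict.loess_fit <- function(object, newdata, ...) {
  Tm <- as.matrix(newdata)
  pl <- loess_plan_cpp(object$coords, Tm, object$span)
  ap <- loess_apply_cpp(object$coords, Tm, pl$idx, pl$kw, pl$bw,
                        object$response, object$weights,
                        rep(-1L, nrow(Tm)), FALSE)
  as.numeric(ap$fitted)
}
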